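test_that("quality thresholds are inclusive and missing data fails", {
  expect_true(passes_quality(20, 0.30)$passed)
  q <- passes_quality(19, 0.5)
  expect_false(q$passed); expect_equal(q$reasons, "LOW_COVERAGE")
  q <- passes_quality(100, 0.29)
  expect_false(q$passed); expect_equal(q$reasons, "LOW_ALT_FRACTION")
  q <- passes_quality(NA, NA)
  expect_setequal(q$reasons, c("LOW_COVERAGE", "LOW_ALT_FRACTION"))
})

test_that("rarity uses the max over databases, inclusively, absent-equals-rare", {
  expect_false(is_rare(c(0.005, 0.012)))
  expect_true(is_rare(0.01))
  expect_true(is_rare(numeric(0)))
  expect_true(is_rare(c(NA, NA)))
  expect_false(is_rare(0.0101))
  expect_error(is_rare(1.2), "outside")
})

test_that("synonymous and unknown classes are not reportable; the six classes are", {
  for (cl in c("missense", "nonsense", "frameshift", "indel", "splice", "CNV"))
    expect_true(is_reportable_class(cl))
  expect_false(is_reportable_class("synonymous"))
  expect_false(is_reportable_class("other"))
})

test_that("the cascade keeps exactly the variants passing all four predicates", {
  # six planted records: two clean, four failing one distinct filter each
  v <- data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    gene = c("PKD1", "PKHD1", "PKD1", "PKD1", "PKD1", "ELSEWHERE"),
    consequence = c("missense_variant", "stop_gained", "synonymous_variant",
                    "missense_variant", "missense_variant",
                    "missense_variant"),
    freq_1kg = c(NA, 0.001, NA, NA, 0.02, NA),
    stringsAsFactors = FALSE)
  g <- data.frame(sample = "P1",
                  depth = c(50L, 60L, 50L, 10L, 50L, 50L),
                  alt_depth = c(25L, 30L, 25L, 5L, 25L, 25L),
                  alt_fraction = 0.5, stringsAsFactors = FALSE)
  vt <- make_vt(v, g)
  fc <- filter_cascade(vt, "P1", gene_set = c("PKD1", "PKHD1"))
  expect_equal(sort(fc$survivors$pos), c(100L, 200L))
  expect_equal(nrow(fc$audit), 6L)
  failed <- fc$audit[!fc$audit$passed, ]
  expect_equal(failed$reasons[failed$key == "1:300:A:G"],
               "SYNONYMOUS_OR_NONREPORTABLE_CLASS")
  expect_equal(failed$reasons[failed$key == "1:400:A:G"], "LOW_COVERAGE")
  expect_equal(failed$reasons[failed$key == "1:500:A:G"],
               "COMMON_POLYMORPHISM")
  expect_equal(failed$reasons[failed$key == "1:600:A:G"], "OFF_PANEL")
  expect_error(filter_cascade(vt, "P1", character(0)), "non-empty")
})

test_that("cascade survivors equal the intersection of the four predicate sets", {
  set.seed(42)
  n <- 200L
  classes <- c("missense", "nonsense", "synonymous", "other", "splice")
  cons <- c(missense = "missense_variant", nonsense = "stop_gained",
            synonymous = "synonymous_variant", other = "intron_variant",
            splice = "splice_donor_variant")
  cls <- sample(classes, n, replace = TRUE)
  v <- data.frame(chrom = "1", pos = seq_len(n) * 10L,
                  gene = sample(c("G1", "G2", "G3", "OFF"), n, replace = TRUE),
                  consequence = unname(cons[cls]),
                  freq_1kg = ifelse(stats::runif(n) < 0.3, NA,
                                    round(stats::runif(n, 0, 0.05), 4)),
                  freq_exac = ifelse(stats::runif(n) < 0.5, NA,
                                     round(stats::runif(n, 0, 0.05), 4)),
                  stringsAsFactors = FALSE)
  depth <- sample(c(10L, 19L, 20L, 21L, 80L), n, replace = TRUE)
  af <- sample(c(0.1, 0.29, 0.3, 0.31, 0.5, 1.0), n, replace = TRUE)
  g <- data.frame(sample = "P1", depth = depth,
                  alt_depth = as.integer(round(depth * af)),
                  alt_fraction = af, stringsAsFactors = FALSE)
  vt <- make_vt(v, g)
  gene_set <- c("G1", "G2", "G3")
  fc <- filter_cascade(vt, "P1", gene_set)

  # independent per-predicate survivor sets, intersected
  keys <- vt$variants$key
  s_class <- keys[vt$variants$variant_class %in%
                    c("missense", "nonsense", "frameshift", "indel",
                      "splice", "CNV")]
  s_qual <- keys[depth >= 20L & af >= 0.3]
  s_rare <- keys[vapply(seq_len(n), function(i) {
    f <- c(v$freq_1kg[i], v$freq_exac[i]); f <- f[!is.na(f)]
    !length(f) || max(f) <= 0.01
  }, logical(1))]
  s_panel <- keys[v$gene %in% gene_set]
  oracle <- Reduce(intersect, list(s_class, s_qual, s_rare, s_panel))
  expect_setequal(fc$survivors$key, oracle)
  # audit covers every input exactly once and passed <=> no reasons
  expect_equal(sort(fc$audit$key), sort(keys))
  expect_equal(fc$audit$passed, !nzchar(fc$audit$reasons))
})

test_that("a tailored-pass C4/C5 stops the analysis; all-C3 falls through to the full panel", {
  p <- tiny_panel()
  # PKD1 is CILIOPATHY-tagged; COL4A5 is GLOMERULAR-only
  v <- data.frame(chrom = c("16", "X"), pos = c(100L, 200L),
                  gene = c("PKD1", "COL4A5"),
                  consequence = c("stop_gained", "missense_variant"),
                  known_pathogenic = c(TRUE, FALSE),
                  stringsAsFactors = FALSE)
  g <- data.frame(sample = c("P1", "P1"), stringsAsFactors = FALSE)
  vt <- make_vt(v, g)
  case <- test_case("CILIOPATHY")
  pr <- two_pass_prioritize(case, p, vt)
  expect_equal(pr$pass_used, "TAILORED")
  # the off-category gene was never classified in the tailored pass
  expect_false("COL4A5" %in% pr$classified$gene)
  expect_true(all(pr$audit$pass == "TAILORED"))

  # demote the ciliopathy variant to C3: full-panel pass engages
  v2 <- v; v2$consequence[1] <- "missense_variant"; v2$known_pathogenic[1] <- FALSE
  vt2 <- make_vt(v2, g)
  pr2 <- two_pass_prioritize(case, p, vt2)
  expect_equal(pr2$pass_used, "FULL")
  # tailored survivors are a subset of full-pass survivors
  tailored_keys <- pr2$audit$key[pr2$audit$pass == "TAILORED" & pr2$audit$passed]
  full_keys <- pr2$audit$key[pr2$audit$pass == "FULL" & pr2$audit$passed]
  expect_true(all(tailored_keys %in% full_keys))
  expect_true("COL4A5" %in% pr2$classified$gene)

  # no usable suspicion: a single full-panel pass
  pr3 <- two_pass_prioritize(test_case("UNKNOWN_ORIGIN"), p, vt)
  expect_equal(pr3$pass_used, "FULL")
  expect_true(all(pr3$audit$pass == "FULL"))
})

test_that("permissive thresholds reduce the cascade to the class filter", {
  v <- data.frame(chrom = "1", pos = c(100L, 200L),
                  gene = c("PKD1", "PKD1"),
                  consequence = c("missense_variant", "synonymous_variant"),
                  freq_1kg = c(0.4, NA), stringsAsFactors = FALSE)
  g <- data.frame(sample = "P1", depth = c(1L, 1L), alt_depth = c(0L, 0L),
                  alt_fraction = c(0.0, 0.0), stringsAsFactors = FALSE)
  vt <- make_vt(v, g)
  cfg <- default_config(min_depth = 0L, min_alt_fraction = 0,
                        max_pop_freq = 1)
  fc <- filter_cascade(vt, "P1", "PKD1", cfg)
  expect_equal(fc$survivors$pos, 100L)
  expect_equal(fc$audit$reasons[2], "SYNONYMOUS_OR_NONREPORTABLE_CLASS")
})
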