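# Independent reference implementations used to cross-check the package.
# These re-derive expected behaviour from first principles (published
# combining table; exhaustive trio enumeration) and deliberately share no
# code with the implementation under test.

# Combining-rule oracle over criterion strength counts.
oracle_combine <- function(evidence) {
  strength <- c(PVS1 = "vs", PS1 = "s", PS2 = "s", PM2 = "m", PM3 = "m",
                PP3 = "p", BP4 = "bp", BS1 = "bs", BA1 = "ba")
  n <- table(factor(strength[evidence],
                    levels = c("vs", "s", "m", "p", "ba", "bs", "bp")))
  c5 <- (n[["vs"]] >= 1 && (n[["s"]] >= 1 || n[["m"]] >= 2 ||
                              (n[["m"]] == 1 && n[["p"]] >= 1) ||
                              n[["p"]] >= 2)) ||
    n[["s"]] >= 2 ||
    (n[["s"]] == 1 && (n[["m"]] >= 3 || (n[["m"]] == 2 && n[["p"]] >= 2) ||
                         (n[["m"]] == 1 && n[["p"]] >= 4)))
  c4 <- (n[["vs"]] >= 1 && n[["m"]] >= 1) ||
    (n[["s"]] == 1 && n[["m"]] >= 1 && n[["m"]] <= 2) ||
    (n[["s"]] == 1 && n[["p"]] >= 2) ||
    n[["m"]] >= 3 || (n[["m"]] == 2 && n[["p"]] >= 2) ||
    (n[["m"]] == 1 && n[["p"]] >= 4) || n[["vs"]] >= 1
  c1 <- n[["ba"]] >= 1 || n[["bs"]] >= 2
  c2 <- (n[["bs"]] == 1 && n[["bp"]] >= 1) || n[["bp"]] >= 2
  if ((c5 || c4) && (c1 || c2)) return("C3")
  if (c5) return("C5")
  if (c4) return("C4")
  if (c1) return("C1")
  if (c2) return("C2")
  "C3"
}

# Trio segregation oracle: enumerated reference logic.
independent_segregation_oracle <- function(zyg, m_gt, f_gt, m_dp, f_dp,
                                           min_dp = 20L) {
  carries <- function(gt) switch(gt, "0/0" = FALSE, "0/1" = TRUE,
                                 "1/1" = TRUE, "none" = NA)
  covered <- function(dp) !is.na(dp) && dp >= min_dp
  mc <- carries(m_gt); fc <- carries(f_gt)
  if (zyg == "HOM") {
    if (identical(mc, FALSE) && covered(m_dp)) return("INCONSISTENT")
    if (identical(fc, FALSE) && covered(f_dp)) return("INCONSISTENT")
  }
  if (is.na(mc) || is.na(fc)) return("UNKNOWN")
  if (mc && fc) return("BIPARENTAL")
  if (mc) return("INHERITED_MATERNAL")
  if (fc) return("INHERITED_PATERNAL")
  if (covered(m_dp) && covered(f_dp)) return("DE_NOVO")
  "UNKNOWN"
}
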