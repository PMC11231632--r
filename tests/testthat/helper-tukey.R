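# Independent pairwise Tukey decisions from the studentized range
# distribution (Tukey-Kramer standard error for unequal n); used to verify
# the compact letter display against a second route.
tukey_decisions <- function(value, group, alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  n <- tapply(value, group, length)
  m <- tapply(value, group, mean)
  df <- sum(n) - k
  s2 <- sum(tapply(value, group, function(v) sum((v - mean(v))^2))) / df
  sig <- matrix(FALSE, k, k, dimnames = list(levels(group), levels(group)))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(s2 / 2 * (1 / n[i] + 1 / n[j]))
    p <- stats::ptukey(abs(m[i] - m[j]) / se, k, df, lower.tail = FALSE)
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  sig
}

# Shared-letter matrix implied by a letter display.
letters_share <- function(tbl) {
  g <- nrow(tbl)
  sets <- strsplit(tbl$letters, "")
  share <- matrix(FALSE, g, g, dimnames = list(tbl$group, tbl$group))
  for (i in 1:g) for (j in 1:g) {
    share[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0
  }
  share
}
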