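# Independent brute-force AMOVA oracle: explicit loops over sample pairs
# and the textbook sums-of-squares / coefficient equations, written
# separately from the package implementation.
amova_oracle <- function(g, loc, reg = NULL) {
  x <- g$calls
  n <- nrow(x)
  L <- ncol(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    d2[i, j] <- sum((x[i, ok] - x[j, ok])^2) * L / sum(ok)
  }
  ss_pairs <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d2[i, j]
    s
  }
  ss_t <- ss_pairs(seq_len(n)) / n
  pops <- split(seq_len(n), loc)
  ss_wp <- sum(vapply(pops, function(idx) ss_pairs(idx) / length(idx), 0))
  n_p <- lengths(pops)
  if (is.null(reg)) {
    P <- length(pops)
    ss_ap <- ss_t - ss_wp
    sig_c <- ss_wp / (n - P)
    nc <- (n - sum(n_p^2) / n) / (P - 1)
    sig_b <- (ss_ap / (P - 1) - sig_c) / nc
    return(list(sigma = c(sig_c, sig_b),
                phi = sig_b / (sig_b + sig_c)))
  }
  grp <- split(seq_len(n), reg)
  n_g <- lengths(grp)
  G <- length(grp)
  P <- length(pops)
  ss_wg <- sum(vapply(grp, function(idx) ss_pairs(idx) / length(idx), 0))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_t - ss_wg
  pop_reg <- vapply(pops, function(idx) unique(reg[idx]), "")
  sig_c <- ss_wp / (n - P)
  np2_by_g <- tapply(n_p^2, pop_reg, sum)
  a_term <- sum(np2_by_g / n_g[names(np2_by_g)])
  nc <- (n - a_term) / (P - G)
  npc <- (a_term - sum(n_p^2) / n) / (G - 1)
  nppc <- (n - sum(n_g^2) / n) / (G - 1)
  sig_b <- (ss_ap / (P - G) - sig_c) / nc
  sig_a <- (ss_ag / (G - 1) - sig_c - npc * sig_b) / nppc
  tot <- sig_a + sig_b + sig_c
  list(sigma = c(sig_c, sig_b, sig_a),
       phi = c((sig_a + sig_b) / tot, sig_b / (sig_b + sig_c), sig_a / tot))
}
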