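# The Jones-Taylor-Thornton (1992) empirical amino-acid substitution model:
# published exchangeability counts (lower triangle, classical
# ARNDCQEGHILKMFPSTWYV order) and stationary frequencies, as parameterized
# in the standard phylogenetics tools.

JTT_EXCHANGE <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  A = 0.0767479232521, R = 0.0516909483091, N = 0.0426449573550,
  D = 0.0515439484561, C = 0.0198029801970, Q = 0.0407519592480,
  E = 0.0618299381701, G = 0.0731519268481, H = 0.0229439770560,
  I = 0.0537609462391, L = 0.0919039080961, K = 0.0586759413241,
  M = 0.0238259761740, F = 0.0401259598740, P = 0.0509009490991,
  S = 0.0687649312351, T = 0.0585649414351, W = 0.0142609857390,
  Y = 0.0321019678980, V = 0.0660049339951)

#' Eigendecomposed JTT rate matrix, cached; scaled to one expected
#' substitution per site per unit time.
#' @noRd
jtt_eigen <- function() {
  if (!is.null(.rscout_cache$jtt_eigen)) return(.rscout_cache$jtt_eigen)
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- JTT_EXCHANGE
  S <- S + t(S)
  pi <- JTT_FREQS[AA20]
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))  # unit expected rate
  # symmetrize for a stable eigendecomposition
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  out <- list(values = e$values,
              left = diag(1 / d) %*% e$vectors,
              right = t(e$vectors) %*% diag(d),
              pi = pi)
  .rscout_cache$jtt_eigen <- out
  out
}

#' JTT transition-probability matrix P(t)
#' @param t evolutionary time (expected substitutions per site).
#' @return 20x20 matrix of P(j at t | i at 0), rows/cols in AA20 order.
#' @export
jtt_probability <- function(t) {
  e <- jtt_eigen()
  P <- e$left %*% diag(exp(e$values * t)) %*% e$right
  P[P < 0] <- 0
  dimnames(P) <- list(AA20, AA20)
  P
}
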