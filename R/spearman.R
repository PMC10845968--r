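# Spearman correlation helpers shared by the network and association
# modules: tie-corrected rho (Pearson on midranks), the two-sided t
# approximation for p, and an exact permutation p for small n.

# cache of permutation matrices, n -> (n! x n)
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  m <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- all_permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  storage.mode(m) <- "integer"
  .perm_cache[[key]] <- m
  m
}

#' Spearman correlation test
#'
#' Tie-corrected Spearman rho (Pearson correlation of midranks) with a
#' two-sided p-value from either the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom, or the
#' exact permutation distribution over all `n!` rank permutations
#' (`method = "exact"`, feasible for `n <= 9`). `method = "auto"` uses the
#' exact test for `n <= exact_max_n` and the t approximation otherwise.
#' `|rho| = 1` gives `p = 0` under the t approximation.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param method `"auto"`, `"tapprox"` or `"exact"`.
#' @param exact_max_n Largest `n` for which `"auto"` picks the exact test.
#' @return A list with `rho`, `p`, `n` and `method`; `rho` and `p` are `NA`
#'   when either vector is constant.
#' @export
spearman_test <- function(x, y, method = c("auto", "tapprox", "exact"),
                          exact_max_n = 9) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stopf("Spearman test needs n >= 4 samples (got %d)", n)
  if (anyNA(x) || anyNA(y)) stopf("x and y must not contain NA")
  rx <- rank(x); ry <- rank(y)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  den <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (den == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- sum(rxc * ryc) / den
  if (method == "auto") method <- if (n <= exact_max_n) "exact" else "tapprox"
  p <- if (method == "exact") {
    perms <- all_permutations(n)
    rho_perm <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / den
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    spearman_p_tapprox(rho, n)
  }
  list(rho = rho, p = p, n = n, method = method)
}

# vectorized two-sided p from the t approximation
spearman_p_tapprox <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho)
  sat <- ok & abs(rho) >= 1 - 1e-12
  p[sat] <- 0
  mid <- ok & !sat
  tt <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}
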