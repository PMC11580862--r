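# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest-remainder rounding
#'
#' Rounds a nonnegative real vector to integers while forcing an exact total.
#' Entries are floored and the leftover units are assigned in order of
#' descending fractional part (ties by lower index). Used to turn real-valued
#' macrostate targets (category counts, agent counts) into integer targets
#' that a synthesis algorithm can satisfy exactly.
#'
#' @param x numeric vector, negative entries are clamped to zero first.
#' @param total integer total the result must sum to; defaults to
#'   `round(sum(x))`.
#' @return integer vector of the same length summing to `total`.
#' @export
round_largest_remainder <- function(x, total = NULL) {
  x <- pmax(as.numeric(x), 0)
  if (is.null(total)) total <- round(sum(x))
  total <- as.integer(round(total))
  if (total < 0) stop("total must be nonnegative")
  fl <- floor(x)
  frac <- x - fl
  d <- total - sum(fl)
  out <- fl
  if (d > 0) {
    ord <- order(-frac, seq_along(x))
    # more units needed than entries: cycle, adding one unit at a time
    i <- 1L
    while (d > 0) {
      out[ord[i]] <- out[ord[i]] + 1
      d <- d - 1
      i <- if (i == length(x)) 1L else i + 1L
    }
  } else if (d < 0) {
    # floors overshoot the requested total; remove from smallest fractions
    ord <- order(frac, seq_along(x))
    i <- 1L
    while (d < 0) {
      if (out[ord[i]] > 0) {
        out[ord[i]] <- out[ord[i]] - 1
        d <- d + 1
      }
      i <- if (i == length(x)) 1L else i + 1L
    }
  }
  as.integer(out)
}

# symmetrize a nearly-symmetric matrix
sym_part <- function(m) (m + t(m)) / 2

# multivariate normal sampler by symmetric eigendecomposition;
# negative eigenvalues (from sampling noise) are clipped at 0
rmvnorm_eig <- function(n, mean, cov) {
  d <- length(mean)
  e <- eigen(sym_part(cov), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * d), n, d)
  out <- z %*% t(e$vectors %*% diag(sqrt(lam), d, d))
  out <- sweep(out, 2, mean, "+")
  colnames(out) <- names(mean)
  out
}

# symmetric psd matrix square root (eigenvalues clipped at 0)
sqrtm_psd <- function(m) {
  e <- eigen(sym_part(m), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), length(lam), length(lam)) %*% t(e$vectors)
}

# sample mean and covariance (denominator n-1) of an ensemble matrix
fit_gaussian <- function(ens) {
  gaussian_belief(colMeans(ens), stats::cov(ens))
}

# count 8-connected components of a logical matrix (flood fill)
count_components_8 <- function(mask) {
  mask <- as.matrix(mask)
  n <- nrow(mask); m <- ncol(mask)
  seen <- matrix(FALSE, n, m)
  ncomp <- 0L
  for (j in seq_len(m)) for (i in seq_len(n)) {
    if (mask[i, j] && !seen[i, j]) {
      ncomp <- ncomp + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  ncomp
}

# derive a child seed from a base seed; stays well below 2^31
mix_seed <- function(seed, salt) {
  ((as.numeric(seed) %% 65011) * 31013 + as.numeric(salt) * 101 + 17) %% 2147483600
}
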