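#' Optical density from transmittance
#'
#' `OD = -log10(max(T, eps))`; absorbances of independent chromophores add
#' in OD space (Beer-Lambert), which is why stain decomposition operates
#' there.
#'
#' @param x numeric array/matrix of transmittance values.
#' @param eps floor applied before the log (default 1e-4).
#' @return array of optical densities, same shape.
#' @export
od_from_transmittance <- function(x, eps = 1e-4) {
  -log10(pmax(x, eps))
}

#' Rank-r NMF by multiplicative updates
#'
#' Factorizes a nonnegative matrix `V (n x m)` as `W (n x r) %*% S (r x m)`
#' by Lee-Seung multiplicative updates minimizing the Frobenius objective
#' `||V - W S||_F`. The objective is non-increasing across iterations;
#' iteration stops when its relative change drops below `tol` or after
#' `max_iter` iterations (the best iterate so far is returned either way,
#' with a warning when `max_iter` is hit before `tol`).
#'
#' @param V nonnegative numeric matrix.
#' @param rank factorization rank (3 for the H&E three-stain model).
#' @param max_iter maximum iterations.
#' @param tol relative-objective-change stopping tolerance.
#' @param seed seed for the nonnegative random initialization.
#' @param W0,S0 optional warm starts (e.g. endmembers fitted on a subsample).
#' @param update_S set FALSE to keep `S0` fixed and solve only for `W`.
#' @return list with `W`, `S`, `objective` (per-iteration trace) and
#'   `converged`.
#' @export
nmf_factorize <- function(V, rank = 3, max_iter = 200, tol = 1e-4,
                          seed = NULL, W0 = NULL, S0 = NULL,
                          update_S = TRUE) {
  stopifnot(is.matrix(V), min(V) >= 0, rank >= 1)
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-12
  with_seed(seed, {
    W <- if (is.null(W0)) matrix(stats::runif(n * rank, 0.1, 1), n, rank) else W0
    S <- if (is.null(S0)) matrix(stats::runif(rank * m, 0.1, 1), rank, m) else S0
    obj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (update_S) {
        S <- S * (crossprod(W, V)) / (crossprod(W, W) %*% S + eps)
      }
      W <- W * (V %*% t(S)) / (W %*% (S %*% t(S)) + eps)
      obj[it] <- sqrt(sum((V - W %*% S)^2))
      if (it > 1 && abs(obj[it - 1] - obj[it]) <= tol * max(obj[it - 1], eps)) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning("NMF reached max_iter (", max_iter,
              ") before the tolerance; returning best iterate")
    list(W = W, S = S, objective = obj, converged = converged)
  })
}

#' NMF-based stain augmentation
#'
#' Decomposes the cube into three stain components (hematoxylin-, eosin-
#' and hemoglobin-like) and perturbs their concentrations: (1) transform to
#' optical density, (2) rank-3 NMF of the pixels-by-bands OD matrix,
#' (3) per component, normalize the abundance map to `[0, 1]`, apply gamma
#' correction `a' = a^gamma` and restore the scale, (4) reconstruct the OD
#' and return `10^(-OD')`, clipped to `[0, 1]`.
#'
#' For cubes with more than `fit_px` pixels the endmember spectra are fitted
#' on a random pixel subsample and full-resolution abundances are then
#' solved with the endmembers held fixed — the decomposition is unchanged in
#' expectation but the fit cost stays bounded.
#'
#' @param cube a transmittance `hypercube`.
#' @param gamma gamma exponent in `[0.5, 1.5]` (1 = plain reconstruction).
#' @param max_iter,tol NMF stopping controls (see [nmf_factorize]).
#' @param seed RNG seed for the NMF initialization and subsample.
#' @param eps transmittance floor before the log.
#' @param fit_px pixel-subsample size for endmember fitting.
#' @return augmented `hypercube`; the fitted endmembers are attached as
#'   attribute `"endmembers"` (3 x B matrix).
#' @export
nmf_stain_augment <- function(cube, gamma, max_iter = 200, tol = 1e-4,
                              seed = NULL, eps = 1e-4, fit_px = 4096) {
  stopifnot(inherits(cube, "hypercube"), gamma > 0)
  if (cube$kind != "transmittance")
    stop("NMF stain augmentation requires a transmittance cube")
  d <- dim(cube$data)
  npx <- d[1] * d[2]
  V <- matrix(od_from_transmittance(cube$data, eps), npx, d[3])
  with_seed(seed, {
    if (npx > fit_px) {
      idx <- sample.int(npx, fit_px)
      fit <- suppressWarnings(
        nmf_factorize(V[idx, , drop = FALSE], 3, max_iter, tol))
      sol <- suppressWarnings(
        nmf_factorize(V, 3, max_iter, tol, S0 = fit$S, update_S = FALSE))
      W <- sol$W; S <- fit$S
    } else {
      fit <- suppressWarnings(nmf_factorize(V, 3, max_iter, tol))
      W <- fit$W; S <- fit$S
    }
    if (gamma != 1) {
      for (j in seq_len(ncol(W))) {
        mx <- max(W[, j])
        if (mx > 0) W[, j] <- (W[, j] / mx)^gamma * mx
      }
    }
    od2 <- W %*% S
    out <- clip01(10^(-od2))
    res <- hypercube(array(out, d), cube$wavelengths, cube$kind)
    attr(res, "endmembers") <- S
    res
  })
}

# best-permutation mean cosine similarity between two r x B spectra matrices
# (r small: permutations enumerated exhaustively) — used to score endmember
# recovery against a known basis.
#' Match recovered endmember spectra to a reference basis
#'
#' Scores a set of recovered spectra against reference spectra by the mean
#' cosine similarity under the best row permutation (enumerated
#' exhaustively; the rank is small).
#'
#' @param S recovered `r x B` spectra matrix.
#' @param ref reference `r x B` spectra matrix.
#' @return list with `mean_cosine`, `perm` (reference row matched to each
#'   recovered row) and `cosines`.
#' @export
match_endmembers <- function(S, ref) {
  stopifnot(nrow(S) == nrow(ref), ncol(S) == ncol(ref))
  r <- nrow(S)
  cs <- matrix(0, r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    cs[i, j] <- sum(S[i, ] * ref[j, ]) /
      sqrt(sum(S[i, ]^2) * sum(ref[j, ]^2) + 1e-300)
  }
  perms <- perms_of(r)
  best <- -Inf; best_p <- NULL
  for (k in seq_len(nrow(perms))) {
    p <- as.integer(perms[k, ])
    v <- mean(cs[cbind(seq_len(r), p)])
    if (v > best) { best <- v; best_p <- p }
  }
  list(mean_cosine = best, perm = unname(best_p),
       cosines = unname(cs[cbind(seq_len(r), best_p)]))
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms_of(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
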