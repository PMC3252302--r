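#' Construct a component set
#'
#' Holds K spatial maps (component x voxel, z-scored over in-mask voxels)
#' and, at subject level, the K time courses. At group level the two-stage
#' PCA destroys the time axis, so `timecourses` is `NULL` and the mixing
#' matrix in the concatenated reduced space is kept instead.
#'
#' @param maps K x voxel matrix.
#' @param timecourses time x K matrix or `NULL`.
#' @param level `"group"` or `"subject"`.
#' @param mixing optional mixing matrix (reduced-space, group level).
#' @return A `component_set`.
#' @export
component_set <- function(maps, timecourses = NULL,
                          level = c("group", "subject"), mixing = NULL) {
  level <- match.arg(level)
  K <- nrow(maps)
  if (K < 1L) stop("need K >= 1 components", call. = FALSE)
  if (!is.null(timecourses) && ncol(timecourses) != K)
    stop("timecourses must have K columns", call. = FALSE)
  structure(list(maps = maps, timecourses = timecourses, K = K,
                 level = level, mixing = mixing),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components x %d voxels (%s level)\n",
              x$K, ncol(x$maps), x$level))
  invisible(x)
}

# eigen-decomposition of the temporal (time x time) second-moment matrix;
# voxels are the samples
temporal_eigen <- function(values) {
  n_vox <- ncol(values)
  c_tt <- tcrossprod(values) / n_vox
  eigen(c_tt, symmetric = TRUE)
}

#' Estimate the number of components by minimum description length
#'
#' Wax-Kailath MDL on the eigenvalues of the temporal covariance, treating
#' in-mask voxels as i.i.d. samples:
#' `MDL(k) = -N (p - k) log(g_k / a_k) + k (2p - k) log(N) / 2`,
#' with `g_k`/`a_k` the geometric/arithmetic means of the `p - k` smallest
#' eigenvalues, `p` the number of time points and `N` the voxel count. No
#' correction for spatial smoothness is applied, so the estimate inflates on
#' heavily smoothed data; the pipeline accepts a fixed `K` override.
#'
#' @param dm a `data_matrix` (time x voxel), or a bare matrix.
#' @return Integer order estimate (argmin over k in 1..p-1), with the MDL
#'   curve in attribute `mdl`.
#' @export
estimate_order_mdl <- function(dm) {
  y <- if (inherits(dm, "data_matrix")) dm$values else dm
  p <- nrow(y); n <- ncol(y)
  if (p < 3L) stop("need at least 3 time points", call. = FALSE)
  if (n < p) stop("need at least as many voxels as time points", call. = FALSE)
  lam <- temporal_eigen(y)$values
  lam <- pmax(lam, .Machine$double.eps)
  if ((max(lam) - min(lam)) / max(lam) < 1e-12) {
    warning("degenerate covariance: all eigenvalues equal; returning 1")
    return(structure(1L, mdl = NA_real_))
  }
  ks <- seq_len(p - 1L)
  mdl <- vapply(ks, function(k) {
    tail_lam <- lam[(k + 1L):p]
    lg <- mean(log(tail_lam))
    la <- log(mean(tail_lam))
    -n * (p - k) * (lg - la) + 0.5 * k * (2 * p - k) * log(n)
  }, numeric(1))
  structure(ks[which.min(mdl)], mdl = mdl)
}

#' Subject-level PCA reduction (stage one)
#'
#' Temporal PCA retaining `p1` components: the basis is the top `p1`
#' eigenvectors of the time x time covariance and
#' `reduced_data = t(basis) %*% values` (p1 x voxel).
#'
#' @param dm a `data_matrix` or time x voxel matrix.
#' @param p1 number of retained temporal dimensions.
#' @return A `pca_reduction` with fields `basis`, `eigenvalues`,
#'   `reduced_data`, `level`.
#' @export
reduce_subject <- function(dm, p1) {
  y <- if (inherits(dm, "data_matrix")) dm$values else dm
  p1 <- as.integer(p1)
  if (p1 > nrow(y))
    stop(sprintf("p1 = %d exceeds %d time points", p1, nrow(y)), call. = FALSE)
  if (p1 < 1L) stop("p1 must be >= 1", call. = FALSE)
  e <- temporal_eigen(y)
  basis <- e$vectors[, seq_len(p1), drop = FALSE]
  structure(list(basis = basis,
                 eigenvalues = pmax(e$values, 0),
                 reduced_data = crossprod(basis, y),
                 level = "subject"),
            class = "pca_reduction")
}

#' Group-level PCA reduction (stage two)
#'
#' Temporally concatenates the subjects' reduced data and reduces to K
#' dimensions by a second PCA.
#'
#' @param reductions list of subject `pca_reduction` objects.
#' @param K group dimension.
#' @return A `pca_reduction` with `level = "group"`; attribute
#'   `subject_rows` records each subject's row block in the concatenation.
#' @export
reduce_group <- function(reductions, K) {
  nv <- vapply(reductions, function(r) ncol(r$reduced_data), integer(1))
  if (length(unique(nv)) != 1L)
    stop("subjects disagree on voxel count", call. = FALSE)
  stacked <- do.call(rbind, lapply(reductions, `[[`, "reduced_data"))
  if (K > nrow(stacked))
    stop("K exceeds the concatenated dimension", call. = FALSE)
  e <- temporal_eigen(stacked)
  basis <- e$vectors[, seq_len(K), drop = FALSE]
  rows <- cumsum(vapply(reductions, function(r) nrow(r$reduced_data), integer(1)))
  structure(list(basis = basis,
                 eigenvalues = pmax(e$values, 0),
                 reduced_data = crossprod(basis, stacked),
                 level = "group"),
            class = "pca_reduction", subject_rows = rows)
}

#' Infomax independent component analysis
#'
#' Natural-gradient infomax with the logistic nonlinearity on whitened data:
#' `dW = lr (I + (1 - 2 y) u' / n) W` over mini-batches, learning rate
#' annealed by 0.9 whenever the angle between successive weight updates
#' exceeds 60 degrees. Maps are the estimated sources over voxels, z-scored,
#' with sign flipped so every map has positive skewness (activation blobs
#' are positive-tailed). On divergence the fit restarts at half the learning
#' rate, at most 3 times.
#'
#' @param reduced a `pca_reduction` (typically from [reduce_group()]); its
#'   `reduced_data` is whitened internally.
#' @param lr0 initial learning rate; default `0.00065 / log(K)`.
#' @param max_iter maximum full passes (default 2048).
#' @param tol relative Frobenius change in W per pass for convergence
#'   (default 1e-7).
#' @param seed RNG seed; fixed seed gives bit-identical results.
#' @return List: `W` (unmixing, acts on whitened data), `whitening`,
#'   `dewhitening`, `mixing` (reduced-space mixing, columns = components),
#'   `components` (a [component_set()], maps z-scored), `iterations`,
#'   `lr_trajectory`, `converged`, `restarts`.
#' @export
infomax <- function(reduced, lr0 = NULL, max_iter = 2048, tol = 1e-7,
                    seed = 1) {
  x <- if (inherits(reduced, "pca_reduction")) reduced$reduced_data else reduced
  d <- nrow(x); n <- ncol(x)
  if (is.null(lr0)) lr0 <- 0.00065 / max(log(d), 0.5)
  ctr <- rowMeans(x)
  xc <- x - ctr
  e <- eigen(tcrossprod(xc) / n, symmetric = TRUE)
  ev <- pmax(e$values, .Machine$double.eps)
  wh <- diag(1 / sqrt(ev), d) %*% t(e$vectors)
  dewh <- e$vectors %*% diag(sqrt(ev), d)
  xw <- wh %*% xc
  # many small blocks per pass: the natural-gradient step is tiny, so the
  # number of updates per pass, not their size, drives convergence speed
  batch <- max(d + 1L, ceiling(min(5 * log(n), 0.3 * n)))
  lr_traj <- numeric(0)
  run_once <- function(lr) {
    w <- diag(d)
    d_prev <- NULL
    iters <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iters <- it
      w0 <- w
      perm <- sample.int(n)
      start <- 1L
      while (start <= n) {
        idx <- perm[start:min(start + batch - 1L, n)]
        nb <- length(idx)
        u <- w %*% xw[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        dw <- lr * (diag(d) + ((1 - 2 * y) %*% t(u)) / nb) %*% w
        w <- w + dw
        if (any(!is.finite(w)) || max(abs(w)) > 1e8)
          return(list(diverged = TRUE))
        start <- start + batch
      }
      d_now <- w - w0
      if (!is.null(d_prev)) {
        num <- sum(d_now * d_prev)
        den <- sqrt(sum(d_now^2) * sum(d_prev^2))
        if (den > 0 && num / den < 0.5) lr <- lr * 0.9  # angle > 60 deg
      }
      d_prev <- d_now
      lr_traj[it] <<- lr
      if (sqrt(sum(d_now^2)) / sqrt(sum(w0^2)) < tol) {
        converged <- TRUE
        break
      }
    }
    list(diverged = FALSE, w = w, iterations = iters, converged = converged,
         lr_final = lr)
  }
  with_seed(seed, {
    restarts <- 0L
    lr <- lr0
    repeat {
      fit <- run_once(lr)
      if (!isTRUE(fit$diverged)) break
      restarts <- restarts + 1L
      if (restarts > 3L)
        stop("infomax diverged after 3 restarts; reduce the learning rate",
             call. = FALSE)
      lr <- lr / 2
      lr_traj <- numeric(0)
    }
    w <- fit$w
    s <- w %*% xw
    flip <- ifelse(row_skewness(s) < 0, -1, 1)
    w <- flip * w
    s <- flip * s
    zmaps <- (s - rowMeans(s)) / apply(s, 1L, stats::sd)
    mixing <- dewh %*% solve(w)
    list(W = w, whitening = wh, dewhitening = dewh, mixing = mixing,
         components = component_set(zmaps, level = "group", mixing = mixing),
         iterations = fit$iterations, lr_trajectory = lr_traj,
         converged = fit$converged, restarts = restarts)
  })
}

#' Match estimated components to reference maps
#'
#' Greedy assignment by maximal absolute spatial correlation; used to
#' resolve ICA's permutation/sign ambiguity against ground truth or
#' templates.
#'
#' @param est K_est x voxel matrix.
#' @param ref K_ref x voxel matrix.
#' @return data.frame: `ref` (row of `ref`), `est` (matched row of `est`),
#'   `correlation` (signed, at the matched pairing).
#' @export
match_components <- function(est, ref) {
  cc <- stats::cor(t(ref), t(est))
  n_ref <- nrow(ref)
  out <- data.frame(ref = seq_len(n_ref), est = NA_integer_,
                    correlation = NA_real_)
  avail <- rep(TRUE, ncol(cc))
  ac <- abs(cc)
  for (step in seq_len(min(n_ref, ncol(cc)))) {
    m <- ac
    m[is.na(m)] <- -Inf
    m[, !avail] <- -Inf
    m[!is.na(out$est), ] <- -Inf
    best <- arrayInd(which.max(m), dim(m))
    out$est[best[1]] <- best[2]
    out$correlation[best[1]] <- cc[best[1], best[2]]
    avail[best[2]] <- FALSE
  }
  out
}
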