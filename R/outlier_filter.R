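# covariance determinant and C-step machinery for the MCD fit

subset_stats <- function(X, idx) {
  mu <- colMeans(X[idx, , drop = FALSE])
  S <- cov(X[idx, , drop = FALSE])
  list(mu = mu, S = S, det = det(S))
}

c_step <- function(X, mu, S, h) {
  d <- tryCatch(mahalanobis(X, mu, S), error = function(e) NULL)
  if (is.null(d)) return(NULL)
  order(d)[seq_len(h)]
}

#' Minimum Covariance Determinant fit
#'
#' Robust location and scatter from the size-`h` subset
#' (`h = ceiling(alpha * n)`) whose sample covariance has the smallest
#' determinant. For small problems every h-subset is examined; for larger
#' ones the classic C-step algorithm is run from many random starts
#' (each C-step re-selects the h points closest in Mahalanobis distance and
#' can only decrease the determinant, so iterating converges).
#'
#' A consistency factor for the scatter (the h-subset covariance
#' underestimates the scatter of a Gaussian) is applied by default.
#'
#' @param X Numeric matrix or data frame (n rows, p columns; rows with
#'   missing values are not allowed here — exclude them upstream).
#' @param alpha Subset fraction (default 0.75).
#' @param n_starts Random starts for the C-step search (default 50).
#' @param max_exhaustive Examine all subsets when `choose(n, h)` is at most
#'   this (default 50000).
#' @param consistency Apply the Gaussian consistency correction to the
#'   scatter (default `TRUE`).
#' @param seed Optional integer seed making the subset search reproducible.
#' @return An object of class `mcd_fit`: list with `mu`, `S`, `h`, `n`,
#'   `alpha`, `det_S` (raw minimal subset-covariance determinant), `subset`
#'   (row indices), `method` (`"exhaustive"` or `"c-step"`), `consistency`.
#' @export
mcd_fit <- function(X, alpha = 0.75, n_starts = 50, max_exhaustive = 50000,
                    consistency = TRUE, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  pf_assert(n >= 10, "MCD fit needs at least 10 rows")
  pf_assert(all(is.finite(X)), "MCD fit requires finite values; exclude incomplete rows")
  h <- as.integer(ceiling(alpha * n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  best <- list(det = Inf, idx = NULL)
  consider <- function(idx) {
    st <- subset_stats(X, idx)
    if (is.finite(st$det) && st$det < best$det) best <<- list(det = st$det, idx = idx, mu = st$mu, S = st$S)
  }

  if (choose(n, h) <= max_exhaustive) {
    method <- "exhaustive"
    combos <- combn(n, h)
    for (j in seq_len(ncol(combos))) consider(combos[, j])
  } else {
    method <- "c-step"
    for (s in seq_len(n_starts)) {
      idx <- sample.int(n, p + 1)
      st <- subset_stats(X, idx)
      # degenerate elemental subset: enlarge until the scatter is usable
      while (!is.finite(st$det) || st$det <= 0) {
        if (length(idx) >= h) break
        idx <- union(idx, sample.int(n, 1))
        st <- subset_stats(X, idx)
      }
      prev_det <- Inf
      for (iter in 1:100) {
        idx <- c_step(X, st$mu, st$S, h)
        if (is.null(idx)) break
        st <- subset_stats(X, idx)
        if (!is.finite(st$det) || st$det >= prev_det * (1 - 1e-12)) break
        prev_det <- st$det
      }
      if (!is.null(idx) && length(idx) == h) consider(idx)
    }
  }

  if (!is.finite(best$det) || is.null(best$idx)) {
    pf_abort(paste0("MCD scatter is singular on every subset examined; ",
                    "jitter the data or remove duplicate rows"))
  }
  S <- best$S
  if (qr(S)$rank < p) {
    pf_abort("MCD scatter is singular; jitter the data or remove duplicate rows")
  }
  if (consistency) {
    q <- h / n
    S <- S * q / stats::pchisq(qchisq(q, df = p), df = p + 2)
  }
  structure(list(mu = best$mu, S = S, h = h, n = n, alpha = alpha,
                 det_S = best$det, subset = sort(best$idx), method = method,
                 consistency = consistency),
            class = "mcd_fit")
}

#' Squared robust Mahalanobis distances
#'
#' The quadratic form `(x - mu)' S^{-1} (x - mu)` with the robust MCD
#' location and scatter, i.e. the squared robust distance.
#'
#' @param X Matrix or data frame with the columns the fit was made on.
#' @param fit An `mcd_fit`.
#' @return Numeric vector of squared distances (NA for incomplete rows).
#' @export
robust_distances <- function(X, fit) {
  X <- as.matrix(X)
  rd <- rep(NA_real_, nrow(X))
  complete <- rowSums(!is.finite(X)) == 0
  rd[complete] <- mahalanobis(X[complete, , drop = FALSE], fit$mu, fit$S)
  rd
}

#' Flag outliers by the scaled chi-square rule
#'
#' A record is an outlier when its squared robust distance exceeds
#' `factor` times the chi-square critical value at `level` with `p` degrees
#' of freedom (default 5 x qchisq(0.999, 3) = 81.33).
#'
#' @param rd Squared robust distances.
#' @param p Degrees of freedom (number of variables, default 3).
#' @param level Chi-square quantile level (default 0.999).
#' @param factor Multiplier on the critical value (default 5).
#' @return A list with `threshold`, logical `is_outlier` (`NA` distances are
#'   never flagged) and `rate` (flagged / non-missing).
#' @export
flag_outliers <- function(rd, p = 3, level = 0.999, factor = 5) {
  threshold <- factor * qchisq(level, df = p)
  is_outlier <- !is.na(rd) & rd > threshold
  list(threshold = threshold, is_outlier = is_outlier,
       rate = sum(is_outlier) / sum(!is.na(rd)))
}

#' Remove anomalous meals by robust distance on (TM, FIM, IBM)
#'
#' Fits the MCD per breed on the meals with complete (TM, FIM, IBM) and drops
#' those whose squared robust distance exceeds the scaled chi-square
#' threshold. First meals (undefined IBM) never enter the fit and are never
#' flagged; invalid (zero-duration) meals are dropped.
#'
#' @param meals Meal tibble from [build_meals()].
#' @param alpha,factor,level,n_starts,seed Passed to [mcd_fit()] /
#'   [flag_outliers()].
#' @return A list with `meals` (kept rows) and `report` (per-breed n, number
#'   flagged, rate, threshold, and the robust location).
#' @export
filter_meal_outliers <- function(meals, alpha = 0.75, factor = 5, level = 0.999,
                                 n_starts = 50, seed = NULL) {
  meals <- meals[meals$valid, , drop = FALSE]
  kept <- list(); report <- list()
  for (brd in unique(meals$breed)) {
    mb <- meals[meals$breed == brd, , drop = FALSE]
    X <- as.matrix(mb[, c("TM", "FIM", "IBM")])
    complete <- rowSums(is.na(X)) == 0
    fit <- mcd_fit(X[complete, , drop = FALSE], alpha = alpha,
                   n_starts = n_starts, seed = seed)
    rd <- robust_distances(X, fit)
    fl <- flag_outliers(rd, p = ncol(X), level = level, factor = factor)
    kept[[brd]] <- mb[!fl$is_outlier, , drop = FALSE]
    report[[brd]] <- list(n = sum(complete), n_first_meals = sum(!complete),
                          flagged = sum(fl$is_outlier), rate = fl$rate,
                          threshold = fl$threshold, mu = as.list(fit$mu))
  }
  list(meals = dplyr::bind_rows(kept), report = report)
}
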