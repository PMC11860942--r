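#' Per-animal trait summary
#'
#' Joins per-animal averages of the post-filter meal traits, the daily meal
#' count, the social-ranking traits and the performance traits into the
#' one-row-per-animal table on which the correlation analysis runs.
#'
#' @param meals Post-filter meal tibble.
#' @param daily Daily traits from [aggregate_daily()].
#' @param rank Rank traits from [social_rank_traits()].
#' @param performance Performance traits from [performance_traits()].
#' @return Tibble, one row per animal: `animal_id`, `pen_id`, `breed`, means
#'   of `TNM`, `NVM`, `TM`, `OTM`, `FIM`, `FR`, `FRM`, `IBM`, then `SW_kg`,
#'   `ADGreg`, `FCR`, `RFI`, `RG`, `RIG` and the rank traits.
#' @export
build_summary <- function(meals, daily, rank, performance) {
  for (nm in c("rank", "performance")) {
    if (anyDuplicated(get(nm)$animal_id) > 0) {
      pf_abort(paste0("duplicate animal rows in ", nm, " table"))
    }
  }
  meals <- meals[meals$valid, , drop = FALSE]
  meal_means <- dplyr::summarise(
    dplyr::group_by(meals, .data$animal_id, .data$pen_id, .data$breed),
    NVM = mean(.data$NVM), TM = mean(.data$TM), OTM = mean(.data$OTM),
    FIM = mean(.data$FIM), FR = mean(.data$FR, na.rm = TRUE),
    FRM = mean(.data$FRM, na.rm = TRUE),
    IBM = if (all(is.na(.data$IBM))) NA_real_ else mean(.data$IBM, na.rm = TRUE),
    .groups = "drop"
  )
  tnm <- dplyr::summarise(dplyr::group_by(daily, .data$animal_id),
                          TNM = mean(.data$TNM), .groups = "drop")
  out <- dplyr::left_join(meal_means, tnm, by = "animal_id")
  out <- dplyr::left_join(out, rank, by = "animal_id")
  perf_cols <- intersect(c("animal_id", "SW_kg", "ADGreg", "FCR", "FCR_tb",
                           "RFI", "RG", "RIG"), names(performance))
  out <- dplyr::left_join(out, performance[, perf_cols], by = "animal_id")
  dplyr::relocate(out, "animal_id", "pen_id", "breed", "TNM")
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' Pairwise-complete Pearson correlations between all numeric traits, with
#' two-sided p-values from the t transform on n - 2 degrees of freedom and a
#' significance flag at `alpha`. Cells with fewer than 3 complete pairs or a
#' zero-variance trait are `NA` and flagged non-significant.
#'
#' @param summary Per-animal summary tibble (see [build_summary()]), or any
#'   tibble of traits keyed by `animal_id`.
#' @param traits Character vector of trait columns; default all numeric
#'   columns.
#' @param alpha Significance threshold (default 0.05).
#' @param p_adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching a plain p < alpha convention).
#' @return Long tibble: `trait_a`, `trait_b`, `r`, `p`, `n`, `significant`,
#'   one row per unordered pair plus the unit diagonal.
#' @export
pearson_matrix <- function(summary, traits = NULL, alpha = 0.05, p_adjust = "none") {
  if (is.null(traits)) {
    traits <- names(summary)[vapply(summary, is.numeric, logical(1))]
  }
  X <- as.data.frame(summary[, traits, drop = FALSE])
  pairs <- expand.grid(a = seq_along(traits), b = seq_along(traits))
  pairs <- pairs[pairs$a <= pairs$b, ]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$a[k]; j <- pairs$b[k]
    x <- X[[i]]; y <- X[[j]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else if (i == j) {
      r <- 1; p <- 0
    } else {
      r <- max(-1, min(1, cor(x[ok], y[ok])))
      if (abs(r) == 1) {
        p <- 0
      } else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * pt(-abs(tt), df = n - 2)
      }
    }
    tibble::tibble(trait_a = traits[i], trait_b = traits[j], r = r, p = p, n = n)
  })
  out <- dplyr::bind_rows(rows)
  padj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(padj) & padj < alpha
  out
}

#' Look up one correlation from a long matrix
#'
#' @param mat Long tibble from [pearson_matrix()].
#' @param a,b Trait names (order-free).
#' @return The matching row (1-row tibble).
#' @export
cor_lookup <- function(mat, a, b) {
  hit <- (mat$trait_a == a & mat$trait_b == b) | (mat$trait_a == b & mat$trait_b == a)
  pf_assert(any(hit), paste0("no correlation recorded for ", a, " vs ", b))
  mat[which(hit)[1], ]
}
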