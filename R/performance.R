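#' Growth rate from feeder-scale readings
#'
#' Ordinary least-squares slope of body weight (g) on age (days), the
#' regression-based average daily gain.
#'
#' @param age_d Numeric vector of ages (days); any origin, only differences
#'   matter.
#' @param weight_g Body weights (g) recorded at those ages.
#' @return Slope in g/day.
#' @export
compute_adg_reg <- function(age_d, weight_g) {
  keep <- !is.na(age_d) & !is.na(weight_g)
  age_d <- age_d[keep]; weight_g <- weight_g[keep]
  pf_assert(length(unique(age_d)) >= 2,
            "ADGreg needs weights at >= 2 distinct ages")
  unname(coef(lm(weight_g ~ age_d))[2])
}

#' Carcass composition percentages
#'
#' Ham, fat and loin percentages of the half carcass, and the lean percentage
#' from the standard prediction equation
#' `Lean% = 25.08 + 0.73 Ham% + 0.87 Loin% - 1.23 Fat%`.
#'
#' @param ham_weight_g,loin_weight_g,back_fat_g,half_carcass_weight_g Carcass
#'   weights in grams (vectors recycle as usual). Missing inputs give missing
#'   outputs.
#' @return Tibble with `Ham_pct`, `Fat_pct`, `Loin_pct`, `Lean_pct`.
#' @export
compute_carcass <- function(ham_weight_g, loin_weight_g, back_fat_g,
                            half_carcass_weight_g) {
  ham <- 100 * ham_weight_g / half_carcass_weight_g
  fat <- 100 * back_fat_g / half_carcass_weight_g
  loin <- 100 * loin_weight_g / half_carcass_weight_g
  tibble::tibble(
    Ham_pct = ham, Fat_pct = fat, Loin_pct = loin,
    Lean_pct = 25.08 + 0.73 * ham + 0.87 * loin - 1.23 * fat
  )
}

#' Feed conversion ratio
#'
#' Primary definition: average daily feed intake over regression growth rate,
#' `FCR = ADFI / ADGreg`. The trait-table variant `FCR_tb = TFI / BWG` is
#' also returned. Non-positive denominators give `NA`.
#'
#' @param ADFI Average daily feed intake (g/day).
#' @param ADGreg Growth rate (g/day).
#' @param TFI Total feed intake (g).
#' @param BWG Body-weight gain (g).
#' @return Tibble with `FCR` and `FCR_tb`.
#' @export
compute_fcr <- function(ADFI, ADGreg, TFI = NA_real_, BWG = NA_real_) {
  tibble::tibble(
    FCR = ifelse(!is.na(ADGreg) & ADGreg > 0, ADFI / ADGreg, NA_real_),
    FCR_tb = ifelse(!is.na(BWG) & BWG > 0, TFI / BWG, NA_real_)
  )
}

#' Residual feed intake, residual gain and residual intake-and-gain
#'
#' Within each breed cohort: `RFI` is the residual of the OLS regression of
#' ADFI on ADGreg, metabolic weight and lean percentage; `RG` is the residual
#' of the mirror regression of ADGreg on ADFI, metabolic weight and lean
#' percentage; `RIG = RG - RFI`. Residuals of an intercept model have zero
#' mean within the fitting cohort by construction. Animals with missing
#' predictors are excluded from the fit and get `NA` residuals.
#'
#' @param cohort Tibble with `animal_id`, `breed`, `ADFI`, `ADGreg`, `MW`,
#'   `Lean_pct`.
#' @return `cohort` with added `RFI`, `RG`, `RIG` (g/day).
#' @export
compute_residual_traits <- function(cohort) {
  fit_resid <- function(df, response, predictors) {
    out <- rep(NA_real_, nrow(df))
    complete <- complete.cases(df[, c(response, predictors)])
    if (sum(complete) < 5) {
      pf_abort(paste0("fewer than 5 complete rows to fit ", response,
                      " residual model in breed ", df$breed[1]))
    }
    X <- df[complete, , drop = FALSE]
    f <- stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
    fit <- lm(f, data = X)
    if (fit$rank < length(predictors) + 1) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      pf_abort(paste0("rank-deficient residual model; collinear column(s): ",
                      paste(bad, collapse = ", ")))
    }
    out[complete] <- unname(resid(fit))
    out
  }
  res <- dplyr::group_modify(dplyr::group_by(cohort, .data$breed), function(df, key) {
    df$breed <- key$breed
    df$RFI <- fit_resid(df, "ADFI", c("ADGreg", "MW", "Lean_pct"))
    df$RG <- fit_resid(df, "ADGreg", c("ADFI", "MW", "Lean_pct"))
    df$breed <- NULL
    df
  })
  res <- dplyr::ungroup(res)
  res$RIG <- res$RG - res$RFI
  res
}

#' Growth, carcass and feed-efficiency traits per animal
#'
#' Fits each animal's growth line on the feeder-scale readings, derives start
#' and end weights from the fitted line at the first and last observed ages
#' (robust to scale noise; set `raw_endpoints = TRUE` for the raw readings),
#' computes metabolic weight `MW = ((BWs + SW)/2)^0.75` (kg^0.75), feed
#' conversion, carcass percentages and the within-breed residual traits.
#'
#' @param visits Cleaned visit tibble (weights and `day_index` are used).
#' @param summary Observation summary from [aggregate_daily()] (`TFI`, `ND`,
#'   `ADFI`).
#' @param roster Roster tibble with carcass columns.
#' @param raw_endpoints Use raw first/last weights instead of fitted values.
#' @return Tibble with one row per animal: `BWs_kg`, `SW_kg`, `BWG_kg`,
#'   `ADGreg`, `MW`, `ADFI`, `TFI`, `ND`, `FCR`, `FCR_tb`, carcass
#'   percentages, `RFI`, `RG`, `RIG`.
#' @export
performance_traits <- function(visits, summary, roster, raw_endpoints = FALSE) {
  age <- visits$day_index + (as.numeric(visits$t_start) %% 86400) / 86400
  growth <- dplyr::group_modify(
    dplyr::group_by(tibble::tibble(animal_id = visits$animal_id, age = age,
                                   weight = visits$weight_g),
                    .data$animal_id),
    function(df, key) {
      fit <- lm(weight ~ age, data = df)
      a0 <- min(df$age); a1 <- max(df$age)
      ends <- if (raw_endpoints) {
        c(df$weight[which.min(df$age)], df$weight[which.max(df$age)])
      } else {
        unname(stats::predict(fit, newdata = data.frame(age = c(a0, a1))))
      }
      tibble::tibble(ADGreg = unname(coef(fit)[2]),
                     BWs_kg = ends[1] / 1000, SW_kg = ends[2] / 1000)
    })
  growth <- dplyr::ungroup(growth)
  out <- dplyr::left_join(summary, growth, by = "animal_id")
  out$BWG_kg <- out$SW_kg - out$BWs_kg
  out$MW <- ((out$BWs_kg + out$SW_kg) / 2)^0.75
  out <- dplyr::bind_cols(out, compute_fcr(out$ADFI, out$ADGreg,
                                           TFI = out$TFI, BWG = 1000 * out$BWG_kg))
  ros <- roster[match(out$animal_id, roster$animal_id), ]
  out <- dplyr::bind_cols(out, compute_carcass(ros$ham_weight_g, ros$loin_weight_g,
                                               ros$back_fat_g, ros$half_carcass_weight_g))
  compute_residual_traits(out)
}
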