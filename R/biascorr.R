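# Bias and total-error statistics for AGB estimation, the m1-m6 family of
# linear VWWD correction models, and leave-one-site-out cross-validation.

# Predictor sets of the model family.
VWWD_MODEL_TERMS <- list(m1 = c("WD_Stu"),
                         m2 = c("WD_Stu", "DBH"),
                         m3 = c("WD_Stu", "DBH", "Sm"),
                         m4 = c("WD_GWD"),
                         m5 = c("WD_GWD", "DBH"),
                         m6 = c("WD_GWD", "DBH", "Sm"))

#' Per-tree relative AGB error, percent
#'
#' b_i = 100 * (AGB_est - AGB_obs) / AGB_obs.
#'
#' @param AGB_est estimated dry biomass, g.
#' @param AGB_obs observed (reference) dry biomass, g.
#' @return signed percent error. Vectorized.
#' @export
relative_error <- function(AGB_est, AGB_obs) {
  stop_if_not(all(AGB_obs > 0), "observed AGB must be positive")
  100 * (AGB_est - AGB_obs) / AGB_obs
}

#' Bias and total-error report for paired AGB estimates
#'
#' Computes the per-tree relative errors b_i, their mean B (the bias, %)
#' and SD, the AGB-level root-mean-square error
#' \code{agb_rmse = sqrt(mean((AGB_est - AGB_obs)^2))} (g), the mean
#' observed biomass MAGB_obs, and the total error
#' \code{CV = 100 * agb_rmse / MAGB_obs} (%).
#'
#' @param AGB_est,AGB_obs paired vectors of estimated and observed AGB, g.
#' @return object of class \code{bias_report}: list with \code{b_i},
#'   \code{B}, \code{sd_b}, \code{agb_rmse}, \code{MAGB_obs}, \code{CV},
#'   \code{n}.
#' @export
bias_report <- function(AGB_est, AGB_obs) {
  stop_if_not(length(AGB_est) == length(AGB_obs),
              "estimate and observation vectors differ in length")
  stop_if_not(length(AGB_obs) >= 1L, "empty input")
  b_i <- relative_error(AGB_est, AGB_obs)
  rmse <- sqrt(mean((AGB_est - AGB_obs)^2))
  magb <- mean(AGB_obs)
  structure(list(b_i = b_i,
                 B = mean(b_i),
                 sd_b = stats::sd(b_i),
                 agb_rmse = rmse,
                 MAGB_obs = magb,
                 CV = 100 * rmse / magb,
                 n = length(b_i)),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("AGB bias report (n = %d)\n", x$n))
  cat(sprintf("  B (mean rel. error): %+.2f%% (sd %.2f%%)\n", x$B, x$sd_b))
  cat(sprintf("  AGB RMSE: %.1f g, MAGB_obs: %.1f g, CV: %.1f%%\n",
              x$agb_rmse, x$MAGB_obs, x$CV))
  invisible(x)
}

#' Fit one of the VWWD correction models m1-m6
#'
#' Ordinary least-squares fit of the tree-level volume-weighted wood
#' density on easily measured predictors: stump WD (m1-m3) or species
#' database WD (m4-m6), optionally adding DBH (m2, m3, m5, m6) and the stem
#' morphology index Sm (m3, m6). Besides the regression metrics (R2,
#' residual SE of the VWWD fit, Gaussian AIC), the fit carries an AGB-level
#' [bias_report()] obtained by predicting VWWD on the fitting set and
#' converting each tree's V_obs to biomass.
#'
#' @param model_id one of \code{"m1"}..\code{"m6"}.
#' @param data tree table with \code{VWWD}, the model's predictors, and
#'   (for the attached bias report) \code{V_obs} and \code{AGB_obs}.
#' @return object of class \code{vwwd_fit}: list with \code{model_id},
#'   \code{coefficients} (estimate, SE, t, p), \code{r_squared},
#'   \code{adj_r_squared}, \code{model_rse} (g cm-3), \code{aic},
#'   \code{n}, \code{bias} (a \code{bias_report} or NULL), and the
#'   underlying \code{lm} fit.
#' @export
fit_vwwd_model <- function(model_id, data) {
  stop_if_not(model_id %in% names(VWWD_MODEL_TERMS),
              "model_id must be one of m1..m6")
  terms <- VWWD_MODEL_TERMS[[model_id]]
  missing_cols <- setdiff(c("VWWD", terms), names(data))
  stop_if_not(length(missing_cols) == 0L,
              "missing column(s) for ", model_id, ": ",
              paste(missing_cols, collapse = ", "))
  stop_if_not(nrow(data) > length(terms) + 1L,
              "not enough trees to fit ", model_id)

  fml <- stats::reformulate(terms, response = "VWWD")
  fit <- stats::lm(fml, data = data)
  if (fit$rank < length(terms) + 1L) {
    stop("rank-deficient design (collinear predictors) in ", model_id,
         call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  coefs <- cbind(term = rownames(coefs), coefs, row.names = NULL)

  bias <- NULL
  if (all(c("V_obs", "AGB_obs") %in% names(data))) {
    vwwd_hat <- stats::predict(fit, newdata = data)
    bias <- bias_report(data$V_obs * vwwd_hat, data$AGB_obs)
  }
  structure(list(model_id = model_id,
                 coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 model_rse = sm$sigma,
                 aic = stats::AIC(fit),
                 n = nrow(data),
                 bias = bias,
                 fit = fit),
            class = "vwwd_fit")
}

#' @export
print.vwwd_fit <- function(x, ...) {
  cat(sprintf("VWWD correction model %s (n = %d)\n", x$model_id, x$n))
  print(x$coefficients, digits = 5)
  cat(sprintf("  R2 = %.3f (adj %.3f), RSE = %.4f g cm-3, AIC = %.1f\n",
              x$r_squared, x$adj_r_squared, x$model_rse, x$aic))
  if (!is.null(x$bias)) {
    cat(sprintf("  AGB bias B = %+.2f%%, CV = %.1f%%\n",
                x$bias$B, x$bias$CV))
  }
  invisible(x)
}

#' Published reference coefficients for the m1-m6 models
#'
#' The coefficient sets calibrated on a published multi-site Central
#' African destructive dataset (822 trees, 51 species), usable through
#' [predict_vwwd()] to correct volume-to-biomass conversions when no local
#' calibration data are available.
#'
#' @return named list of coefficient vectors, one per model; each has an
#'   \code{(Intercept)} followed by the model's predictor coefficients.
#' @export
vwwd_presets <- function() {
  list(m1 = c("(Intercept)" = 0.07842, WD_Stu = 0.78915),
       m2 = c("(Intercept)" = 0.05455, WD_Stu = 0.78326, DBH = 0.00048),
       m3 = c("(Intercept)" = 0.10013, WD_Stu = 0.77299, DBH = 0.00042,
              Sm = -0.05819),
       m4 = c("(Intercept)" = 0.17210, WD_GWD = 0.63638),
       m5 = c("(Intercept)" = 0.13406, WD_GWD = 0.63614, DBH = 0.00067),
       m6 = c("(Intercept)" = 0.18233, WD_GWD = 0.62656, DBH = 0.00060,
              Sm = -0.06258))
}

#' Predict VWWD from a fitted model or a preset
#'
#' Linear combination of the model coefficients with the supplied
#' predictors. Accepts a \code{vwwd_fit} from [fit_vwwd_model()], a model
#' id (\code{"m1"}..\code{"m6"}, resolved against [vwwd_presets()]) or a
#' named coefficient vector with an \code{(Intercept)} entry.
#'
#' @param object a \code{vwwd_fit}, a preset id, or coefficients.
#' @param newdata data.frame carrying the required predictor columns.
#' @return numeric vector of predicted VWWD, g cm-3.
#' @export
predict_vwwd <- function(object, newdata) {
  if (inherits(object, "vwwd_fit")) {
    coefs <- stats::coef(object$fit)
  } else if (is.character(object) && length(object) == 1L) {
    presets <- vwwd_presets()
    stop_if_not(object %in% names(presets),
                "unknown preset: ", object)
    coefs <- presets[[object]]
  } else if (is.numeric(object) && !is.null(names(object))) {
    coefs <- object
  } else {
    stop("object must be a vwwd_fit, a preset id, or named coefficients",
         call. = FALSE)
  }
  stop_if_not("(Intercept)" %in% names(coefs),
              "coefficients must include an (Intercept)")
  terms <- setdiff(names(coefs), "(Intercept)")
  missing_cols <- setdiff(terms, names(newdata))
  stop_if_not(length(missing_cols) == 0L,
              "newdata missing predictor(s): ",
              paste(missing_cols, collapse = ", "))
  pred <- rep(coefs[["(Intercept)"]], nrow(newdata))
  for (tm in terms) pred <- pred + coefs[[tm]] * newdata[[tm]]
  pred
}

#' Leave-one-site-out cross-validation of a VWWD model
#'
#' For each site, the model is calibrated on all other sites and used to
#' predict VWWD (and from it AGB) for the focal site's trees; bias B and
#' total error CV are reported per site and pooled over all out-of-site
#' predictions.
#'
#' @param data tree table with \code{site}, \code{VWWD}, \code{V_obs},
#'   \code{AGB_obs} and the model's predictors.
#' @param model_id one of \code{"m1"}..\code{"m6"}.
#' @return list with \code{per_site} (data.frame: site, n, B, CV) and
#'   \code{pooled} (a \code{bias_report} over all held-out trees).
#' @export
loso_crossval <- function(data, model_id = "m1") {
  stop_if_not("site" %in% names(data), "data must have a site column")
  sites <- unique(data$site)
  stop_if_not(length(sites) >= 2L,
              "leave-one-site-out needs at least 2 sites")
  p <- length(VWWD_MODEL_TERMS[[model_id]]) + 1L
  est_all <- obs_all <- numeric(0L)
  rows <- vector("list", length(sites))
  for (k in seq_along(sites)) {
    s <- sites[k]
    train <- data[data$site != s, , drop = FALSE]
    test <- data[data$site == s, , drop = FALSE]
    if (nrow(train) <= p) {
      stop("too few trees to calibrate when leaving out site ", s,
           call. = FALSE)
    }
    fit <- fit_vwwd_model(model_id, train)
    vwwd_hat <- predict_vwwd(fit, test)
    rep_s <- bias_report(test$V_obs * vwwd_hat, test$AGB_obs)
    est_all <- c(est_all, test$V_obs * vwwd_hat)
    obs_all <- c(obs_all, test$AGB_obs)
    rows[[k]] <- data.frame(site = s, n = nrow(test),
                            B = rep_s$B, CV = rep_s$CV,
                            stringsAsFactors = FALSE)
  }
  list(per_site = do.call(rbind, rows),
       pooled = bias_report(est_all, obs_all),
       model_id = model_id)
}
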