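# Covariate-adjusted w-scoring of regional volumes against a control cohort.

META_COLUMNS <- c("subject_id", "visit_index", "group", "diagnosis",
                  "age", "sex", "tiv", "scanner", "interval_years",
                  "true_subtype", "true_stage", "scan_year")

#' Identify the ROI volume columns of a regional volume table
#'
#' Volume tables carry one row per subject-visit with covariate columns
#' (`subject_id`, `visit_index`, `group`, `diagnosis`, `age`, `sex`, `tiv`,
#' `scanner`, ...) followed by one numeric column per region of interest.
#' Every column not recognised as metadata is treated as an ROI.
#'
#' @param table a regional volume data frame.
#' @return character vector of ROI column names.
#' @export
roi_columns <- function(table) {
  setdiff(names(table), META_COLUMNS)
}

validate_volume_table <- function(table, rois, covariates) {
  for (v in c("tiv", rois)) {
    if (!v %in% names(table)) stop_config("missing column '%s'", v)
    if (any(!is.finite(table[[v]])) || any(table[[v]] <= 0))
      stop_config("column '%s' must be strictly positive and finite", v)
  }
  for (v in covariates)
    if (any(is.na(table[[v]])))
      stop_config("missing values in covariate '%s' (no silent imputation)", v)
  invisible(TRUE)
}

# Design matrix under reference-level encoding using stored factor levels.
# Single-level factors contribute no column (absorbed by the intercept).
cov_design <- function(table, covariates, levels) {
  n <- nrow(table)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in covariates) {
    if (v %in% names(levels)) {
      lev <- levels[[v]]
      val <- as.character(table[[v]])
      unseen <- setdiff(unique(val), lev)
      if (length(unseen))
        stop_config("unseen %s category: %s", v,
                    paste(unseen, collapse = ", "))
      for (l in lev[-1L]) cols[[paste0(v, l)]] <- as.numeric(val == l)
    } else {
      cols[[v]] <- as.numeric(table[[v]])
    }
  }
  do.call(cbind, cols)
}

#' Fit the control-referenced covariate model for w-scoring
#'
#' Per-ROI ordinary least squares of volume on the listed covariates, fitted
#' on control subjects only (one baseline row each). Categorical covariates
#' (`sex`, `scanner`) enter with reference-level encoding; `age` and `tiv`
#' enter linearly. The per-ROI residual standard deviation (sample SD of the
#' control residuals) is the w-score denominator.
#'
#' @param controls regional volume table of control rows (if a `group`
#'   column is present, only `group == "control"` rows are used).
#' @param covariates covariate column names; categorical ones are detected as
#'   non-numeric columns. Default `c("sex", "age", "tiv", "scanner")`.
#' @param rois ROI column names; defaults to [roi_columns()].
#' @param min_residual_sd floor applied to the residual SD to guard exact
#'   fits (default 1e-8).
#' @return An object of class `covariate_model` with per-ROI `coefficients`,
#'   `residual_sd`, the covariate `levels` encoding map and `control_n`.
#' @export
fit_control_model <- function(controls,
                              covariates = c("sex", "age", "tiv", "scanner"),
                              rois = NULL, min_residual_sd = 1e-8) {
  if ("group" %in% names(controls))
    controls <- controls[controls$group == "control", , drop = FALSE]
  if (anyDuplicated(controls$subject_id))
    stop_config("controls must contribute one (baseline) row per subject")
  if (is.null(rois)) rois <- roi_columns(controls)
  validate_volume_table(controls, rois, covariates)
  levels <- list()
  for (v in covariates)
    if (!is.numeric(controls[[v]]))
      levels[[v]] <- sort(unique(as.character(controls[[v]])))
  X <- cov_design(controls, covariates, levels)
  if (nrow(X) < ncol(X) + 2L)
    stop_config("need at least %d control rows for %d regression parameters",
                ncol(X) + 2L, ncol(X))
  Y <- as.matrix(controls[, rois, drop = FALSE])
  fit <- stats::lm.fit(X, Y)
  if (fit$rank < ncol(X))
    stop_config("collinear covariates: design matrix is rank deficient")
  res <- as.matrix(fit$residuals)
  rsd <- pmax(apply(res, 2L, stats::sd), min_residual_sd)
  coef <- as.matrix(fit$coefficients)
  colnames(coef) <- rois
  structure(
    list(coefficients = coef, residual_sd = stats::setNames(rsd, rois),
         covariates = covariates, levels = levels, rois = rois,
         control_n = nrow(controls), min_residual_sd = min_residual_sd,
         source = "fitted"),
    class = "covariate_model"
  )
}

#' @export
print.covariate_model <- function(x, ...) {
  cat(sprintf("Covariate model (%s): %d ROIs, covariates %s, %s control rows\n",
              x$source, length(x$rois), paste(x$covariates, collapse = "+"),
              x$control_n %||% "?"))
  invisible(x)
}

predict_volumes <- function(model, table) {
  X <- cov_design(table, model$covariates, model$levels)
  X %*% model$coefficients
}

#' Compute covariate-adjusted w-scores
#'
#' The w-score of a visit is (observed - predicted) / residual SD, with the
#' prediction from a control-fitted [fit_control_model()]. With
#' `sign_flip = TRUE` (default) scores are negated so that atrophy (volume
#' loss) yields positive, increasing abnormality, matching ascending severity
#' thresholds.
#'
#' @param table regional volume table (patients and/or controls; follow-up
#'   visits are scored with their own age/scanner covariate values).
#' @param model a `covariate_model`.
#' @param sign_flip negate raw scores so larger = more abnormal (default TRUE).
#' @return An object of class `wscore_matrix`: list with `scores`
#'   (subject-visits x ROIs), `meta` (subject_id, visit_index, group,
#'   diagnosis) and `model_ref`.
#' @export
compute_wscores <- function(table, model, sign_flip = TRUE) {
  validate_volume_table(table, model$rois, model$covariates)
  pred <- predict_volumes(model, table)
  obs <- as.matrix(table[, model$rois, drop = FALSE])
  w <- sweep(obs - pred, 2L, model$residual_sd, `/`)
  if (sign_flip) w <- -w
  meta <- data.frame(
    subject_id = as.character(table$subject_id),
    visit_index = if ("visit_index" %in% names(table))
      as.integer(table$visit_index) else 1L,
    group = if ("group" %in% names(table))
      as.character(table$group) else "patient",
    diagnosis = if ("diagnosis" %in% names(table))
      as.character(table$diagnosis) else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(w) <- paste(meta$subject_id, meta$visit_index, sep = ".")
  structure(list(scores = w, meta = meta,
                 model_ref = sprintf("%s covariate model, %s controls",
                                     model$source, model$control_n %||% "?")),
            class = "wscore_matrix")
}

#' @export
print.wscore_matrix <- function(x, ...) {
  cat(sprintf("w-score matrix: %d subject-visits x %d ROIs (%s)\n",
              nrow(x$scores), ncol(x$scores), x$model_ref))
  invisible(x)
}

#' Subset a w-score matrix by row, keeping metadata aligned
#'
#' @param W a `wscore_matrix`.
#' @param idx row indices or a logical vector over subject-visits.
#' @return a `wscore_matrix` with the selected rows.
#' @export
subset_wscores <- function(W, idx) {
  structure(list(scores = W$scores[idx, , drop = FALSE],
                 meta = W$meta[idx, , drop = FALSE],
                 model_ref = W$model_ref),
            class = "wscore_matrix")
}
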