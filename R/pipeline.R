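# Prediction pipeline: 143-column design matrix, per-CM subset logistic
# models, attribute-set-wise stepwise main model with backward removal, and
# patient-level predicted probabilities of death (PDeathLabs).

#' Candidate predictor column names
#'
#' One column per measurement x parameter, named `<CM><Parameter>` (e.g.
#' `SBPValue1`, `A1cNumClust`), ordered measurement-major with parameters in
#' attribute order. With the full 11 measurements this is the 13 x 11 = 143
#' candidate set.
#'
#' @param cms Measurement codes (default all 11).
#' @return Character vector of column names.
#' @export
candidate_column_names <- function(cms = cm_codes()) {
  as.vector(vapply(cms, function(cm) paste0(cm, parameter_names()),
                   character(13)))
}

#' Build the candidate design matrix for a cohort
#'
#' Truncates every series at the index date minus the blackout window, runs
#' the parameter engine per patient x measurement, and spreads the results
#' into one row per patient with `<CM><Parameter>` columns, the outcome and
#' the baseline covariates. Parameters that are undefined for a patient
#' (including all 13 columns of a measurement the patient never had)
#' propagate as missing cells.
#'
#' @param measurements Long measurement table (`patient_id`, `cm_name`,
#'   `day`, `value`) or a `synthetic_cohort`.
#' @param patients Patient table with `patient_id`, `index_day`, `death60`
#'   and optionally `age`, `charl_2yr`, `charl_ever`, `elix_2yr`,
#'   `elix_ever`. Ignored when `measurements` is a `synthetic_cohort`.
#' @param targets Named list of [target_spec()].
#' @param blackout_days Days before the index date to exclude (default 14).
#' @param mode Time-weighted-average mode (see [compute_time_wt_avg()]).
#' @return A `data.table` of class `design_matrix`: `patient_id`, `death60`,
#'   covariates, then the candidate columns (attribute
#'   `candidate_cols` lists them).
#' @export
build_design_matrix <- function(measurements, patients = NULL,
                                targets = default_targets(),
                                blackout_days = 14,
                                mode = c("full", "abnormal")) {
  mode <- match.arg(mode)
  if (inherits(measurements, "synthetic_cohort")) {
    patients <- measurements$patients
    measurements <- measurements$measurements
  }
  if (is.null(patients))
    stop("build_design_matrix: a patient table is required")
  meas <- as.data.table(measurements)
  pats <- as.data.table(patients)
  stopifnot(all(c("patient_id", "index_day", "death60") %in% names(pats)))
  cms <- names(targets)
  unknown <- setdiff(unique(meas$cm_name), cms)
  if (length(unknown))
    stop("unknown measurement(s) in cohort: ", paste(unknown, collapse = ", "))

  meas <- pats[, .(patient_id, index_day)][meas, on = "patient_id"]
  if (anyNA(meas$index_day))
    stop("measurements for patients missing from the patient table")
  meas <- meas[day <= index_day - blackout_days]

  cand <- candidate_column_names(cms)
  covars <- intersect(c("age", "charl_2yr", "charl_ever", "elix_2yr",
                        "elix_ever"), names(pats))
  dm <- pats[, c("patient_id", "death60", covars), with = FALSE]

  if (nrow(meas)) {
    params <- derive_parameter_table(meas, targets, mode)
    for (j in parameter_names())
      data.table::set(params, j = j, value = as.numeric(params[[j]]))
    for (cm in intersect(cms, unique(params$cm_name))) {
      block <- params[cm_name == cm,
                      c("patient_id", parameter_names()), with = FALSE]
      setnames(block, parameter_names(), paste0(cm, parameter_names()))
      dm <- block[dm, on = "patient_id"]
    }
  }
  for (cc in setdiff(cand, names(dm))) dm[, (cc) := NA_real_]
  setcolorder(dm, c("patient_id", "death60", covars, cand))
  setattr(dm, "candidate_cols", cand)
  setattr(dm, "cms", cms)
  data.table::setattr(dm, "class", c("design_matrix", class(dm)))
  dm[]
}

#' Candidate columns of a design matrix
#' @param dm A `design_matrix`.
#' @return Character vector of candidate predictor column names.
#' @export
candidate_columns <- function(dm) attr(dm, "candidate_cols", exact = TRUE)

#' Case-wise deletion
#'
#' Removes every row with a missing value in any of the named columns (the
#' semantics used for the subset regressions and the main model: analyses
#' pertain to patients with observed values for every variable in the fit).
#'
#' @param dm A `design_matrix` (or any data.table).
#' @param columns Columns that must be complete.
#' @return The retained rows, with attribute `n_used` = number retained.
#' @export
casewise_complete <- function(dm, columns) {
  missing_cols <- setdiff(columns, names(dm))
  if (length(missing_cols))
    stop("casewise_complete: unknown column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- complete.cases(as.data.frame(dm)[, columns, drop = FALSE])
  out <- dm[keep]
  setattr(out, "candidate_cols", attr(dm, "candidate_cols", exact = TRUE))
  setattr(out, "n_used", sum(keep))
  out
}

# ---- maximum-likelihood logistic fits on a numeric matrix -----------------

fit_logistic <- function(x, y, term_names = colnames(x)) {
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X) <- c("(Intercept)", term_names)
  boundary <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        boundary <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- ncol(X)
  coefs <- fit$coefficients
  rank <- fit$rank
  se <- rep(NA_real_, p)
  if (rank > 0) {
    piv <- fit$qr$pivot[seq_len(rank)]
    Rm <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
    se[piv] <- sqrt(diag(chol2inv(Rm)))
  }
  z <- coefs / se
  pval <- 2 * pnorm(-abs(z))
  halfw <- qnorm(0.975) * se
  structure(list(
    terms = colnames(X),
    coef = unname(coefs), se = unname(se), z = unname(z),
    p_value = unname(pval),
    ci_lo = unname(coefs - halfw), ci_hi = unname(coefs + halfw),
    n_used = length(y),
    converged = isTRUE(fit$converged),
    boundary = boundary,
    deviance = fit$deviance,
    fitted = fit$fitted.values
  ), class = "ll_fit")
}

#' @export
print.ll_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<ll_fit> logistic model, %d term(s) + intercept, n=%d%s\n",
              length(x$terms) - 1L, x$n_used,
              if (x$converged) "" else "  [DID NOT CONVERGE]"))
  print(data.frame(Parameter = x$terms,
                   Coefficient = round(x$coef, digits),
                   StdErr = round(x$se, digits),
                   pValue = signif(x$p_value, 3),
                   CI95lo = round(x$ci_lo, digits),
                   CI95hi = round(x$ci_hi, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Tidy coefficient table of a logistic fit
#'
#' @param fit An `ll_fit`.
#' @return `data.table` with columns `Parameter`, `Coefficient`, `StdErr`,
#'   `pValue`, `CI95lo`, `CI95hi`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "ll_fit"))
  data.table(Parameter = fit$terms, Coefficient = fit$coef,
             StdErr = fit$se, pValue = fit$p_value,
             CI95lo = fit$ci_lo, CI95hi = fit$ci_hi)
}

#' Subset logistic regression for one measurement
#'
#' Fits death on the 13 parameters of a single measurement (maximum
#' likelihood, after case-wise deletion on those 13 columns) and evaluates
#' the in-sample AUROC of the fitted probabilities. Non-convergence or
#' separation is reported in the result (`converged = FALSE`), never
#' silently ignored.
#'
#' @param dm A `design_matrix`.
#' @param cm Measurement code.
#' @param outcome Outcome column name (default `death60`).
#' @return List with `fit` (`ll_fit`) and `roc` (`ll_roc`; `NULL` when the
#'   model did not converge).
#' @export
subset_regression <- function(dm, cm, outcome = "death60") {
  cols <- paste0(cm, parameter_names())
  cc <- casewise_complete(dm, c(cols, outcome))
  if (nrow(cc) == 0)
    stop("subset_regression(", cm, "): no complete cases")
  y <- cc[[outcome]]
  if (length(unique(y)) < 2)
    stop("subset_regression(", cm, "): single-class outcome after deletion")
  x <- as.matrix(as.data.frame(cc)[, cols, drop = FALSE])
  fit <- fit_logistic(x, y, cols)
  # a fit on the boundary (fitted probabilities numerically 0/1, e.g. under
  # separation) is reported as non-converged for a subset model
  fit$converged <- fit$converged && !fit$boundary
  roc <- if (fit$converged)
    compute_auroc(fit$fitted, y, ids = cc$patient_id) else NULL
  list(cm = cm, fit = fit, roc = roc, n_used = nrow(cc))
}

#' Stepwise main model with attribute-set-wise entry and backward removal
#'
#' Builds the main predictive model from all candidate columns. Case-wise
#' deletion over the full candidate set is applied once, up front, so the
#' model is developed on patients with complete data. Modelling starts with
#' the current-control set (the most recent values); the remaining attribute
#' sets enter in succession. After each set enters, terms are removed one at
#' a time - worst (largest) Wald p-value first, refitting after every drop -
#' until every retained term has p < `alpha`; terms that entered earlier can
#' be removed at any later stage. "Adjusted p-value" is the
#' covariate-adjusted Wald p-value from the multivariable fit (no
#' multiplicity correction). Aliased (collinear) terms are dropped with a
#' note. Non-convergence at any stage produces a diagnostic naming the
#' attribute set.
#'
#' @param dm A `design_matrix`.
#' @param attr_order Permutation of the 7 attribute labels, beginning with
#'   `"control"` (see [attribute_order()]).
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @param outcome Outcome column name.
#' @return An `ll_fit` for the final model, with extra fields `steps` (log
#'   of entries and removals) and `retained` (final term names).
#' @export
stepwise_main_model <- function(dm, attr_order = attribute_order(),
                                alpha = 0.05, outcome = "death60") {
  stopifnot(setequal(attr_order, attribute_order()))
  if (attr_order[1] != "control")
    stop("stepwise_main_model: modelling must start with the most recent",
         " values (attribute set 'control')")
  if (!(alpha > 0 && alpha <= 1))
    stop("stepwise_main_model: alpha must be in (0, 1]")
  cand <- candidate_columns(dm)
  if (is.null(cand)) stop("not a design_matrix (no candidate columns)")
  cc <- casewise_complete(dm, c(cand, outcome))
  if (nrow(cc) == 0)
    stop("stepwise_main_model: no complete cases over the candidate set")
  y <- cc[[outcome]]
  if (length(unique(y)) < 2)
    stop("stepwise_main_model: single-class outcome after deletion")
  xall <- as.matrix(as.data.frame(cc)[, cand, drop = FALSE])

  attr_of <- parameter_attributes()
  param_of <- function(col) {
    for (p in parameter_names()) if (endsWith(col, p)) return(p)
    stop("unrecognized candidate column: ", col)
  }
  col_attr <- vapply(cand, function(cc_) attr_of[[param_of(cc_)]],
                     character(1))

  in_model <- character()
  steps <- list()
  fit <- NULL
  for (set_name in attr_order) {
    entering <- cand[col_attr == set_name]
    in_model <- c(in_model, entering)
    steps[[length(steps) + 1L]] <- list(action = "enter", set = set_name,
                                        terms = entering)
    repeat {
      fit <- fit_logistic(xall[, in_model, drop = FALSE], y, in_model)
      if (!fit$converged)
        warning("stepwise_main_model: fit did not converge after entering",
                " attribute set '", set_name, "' (",
                length(in_model), " terms in model)")
      if (fit$boundary)
        steps[[length(steps) + 1L]] <- list(action = "boundary_fit",
                                            set = set_name,
                                            terms = in_model)
      # aliased terms are non-identifiable here: remove them immediately
      aliased <- fit$terms[-1][is.na(fit$coef[-1])]
      if (length(aliased)) {
        in_model <- setdiff(in_model, aliased)
        steps[[length(steps) + 1L]] <- list(action = "drop_aliased",
                                            set = set_name, terms = aliased)
        next
      }
      pv <- fit$p_value[-1]
      worst <- which.max(pv)
      if (length(worst) && pv[worst] >= alpha && length(in_model) > 0) {
        dropped <- in_model[worst]
        in_model <- in_model[-worst]
        steps[[length(steps) + 1L]] <- list(action = "drop", set = set_name,
                                            terms = dropped,
                                            p = pv[worst])
        if (!length(in_model)) {
          fit <- fit_logistic(xall[, character(0), drop = FALSE], y,
                              character(0))
          break
        }
        next
      }
      break
    }
  }
  fit$steps <- steps
  fit$retained <- in_model
  fit$n_used <- nrow(cc)
  fit$patient_id <- cc$patient_id
  fit
}

#' Predicted probability of death from the fitted model
#'
#' Applies the logistic inverse link to the fitted linear predictor for each
#' patient. Rows must be complete for every term in the fit.
#'
#' @param fit An `ll_fit` (e.g. from [stepwise_main_model()]).
#' @param dm A `design_matrix` (or any table with the fit's term columns).
#' @return Named numeric vector of probabilities in (0, 1), named by
#'   `patient_id` when present.
#' @export
predict_pdeathlabs <- function(fit, dm) {
  stopifnot(inherits(fit, "ll_fit"))
  terms <- setdiff(fit$terms, "(Intercept)")
  missing_cols <- setdiff(terms, names(dm))
  if (length(missing_cols))
    stop("predict_pdeathlabs: required column(s) absent: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(as.data.frame(dm)[, terms, drop = FALSE])
  if (anyNA(x))
    stop("predict_pdeathlabs: rows are not case-wise complete for the",
         " model terms")
  beta <- fit$coef
  lp <- beta[1] + if (length(terms)) drop(x %*% beta[-1]) else
    rep(0, nrow(x))
  pr <- plogis(lp)
  if ("patient_id" %in% names(dm)) names(pr) <- dm$patient_id
  pr
}

#' Single-factor baseline model
#'
#' One-predictor logistic model for a baseline covariate (age at diagnosis
#' or a comorbidity score) and the AUROC of its predicted probabilities.
#' Because the fitted probability is a monotone transform of the covariate,
#' the AUROC equals that of the raw covariate.
#'
#' @param dm A `design_matrix`.
#' @param covariate Covariate column name.
#' @param outcome Outcome column name.
#' @return List with `fit` (`ll_fit`) and `roc` (`ll_roc`).
#' @export
single_factor_model <- function(dm, covariate, outcome = "death60") {
  if (!covariate %in% names(dm))
    stop("single_factor_model: no such covariate: ", covariate)
  cc <- casewise_complete(dm, c(covariate, outcome))
  x <- cc[[covariate]]
  y <- cc[[outcome]]
  if (length(unique(x)) < 2)
    stop("single_factor_model(", covariate,
         "): constant covariate, discrimination undefined")
  if (length(unique(y)) < 2)
    stop("single_factor_model(", covariate, "): single-class outcome")
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, covariate)), y,
                      covariate)
  list(covariate = covariate, fit = fit,
       roc = compute_auroc(fit$fitted, y, ids = cc$patient_id),
       n_used = nrow(cc))
}
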