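# Regression formulas mapping trial-wise covariates (and the latent conflict
# term) onto decision parameters.

REGRESSION_TARGETS <- c("a", "v", "t", "z", "alpha")

#' Parse a parameter regression formula
#'
#' Formulas have the form `"<param> ~ <term> [+ <term> ...]"` where `param`
#' is one of `a`, `v`, `t`, `z`, `alpha`. Terms may combine covariates with
#' `*` (main effects plus all interactions) or `:` (the interaction only),
#' exactly as in R model formulas; a leading `0 +` drops the intercept. The
#' reserved name `conflict` refers to the latent trial-wise conflict series
#' (see [conflict_series()]); all other names must be data columns.
#'
#' @param text Formula string, e.g. `"a ~ neural"` or
#'   `"a ~ stn*theta*conflict + presma*conflict"`.
#' @param columns Character vector of available covariate column names.
#' @return A `regression_spec`: list with `target`, `terms` (expanded, in
#'   order), and `intercept` flag.
#' @export
parse_formula <- function(text, columns = character()) {
  if (!is.character(text) || length(text) != 1 || !grepl("~", text, fixed = TRUE))
    abort_parse(sprintf("not a formula: '%s' (expected '<param> ~ <terms>')", text))
  parts <- strsplit(text, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort_parse(sprintf("malformed formula: '%s'", text))
  target <- trimws(parts[1])
  if (!target %in% REGRESSION_TARGETS)
    abort_parse(sprintf(
      "unknown parameter '%s' at position 1 of '%s' (must be one of %s)",
      target, text, paste(REGRESSION_TARGETS, collapse = ", ")))
  rhs <- trimws(parts[2])
  f <- tryCatch(stats::as.formula(paste("~", rhs)),
                error = function(e) abort_parse(
                  sprintf("cannot parse terms '%s': %s", rhs, conditionMessage(e))))
  tm <- stats::terms(f)
  vars <- all.vars(f)
  for (v in vars) {
    if (!v %in% c(columns, "conflict"))
      abort_parse(sprintf("unknown covariate '%s' at position %d of '%s'",
                          v, as.integer(regexpr(v, text, fixed = TRUE)), text))
  }
  structure(list(target = target,
                 terms = attr(tm, "term.labels"),
                 intercept = attr(tm, "intercept") == 1),
            class = "regression_spec")
}

# Coefficient names of a regression spec, in design-matrix order.
regression_coef_names <- function(rspec) {
  c(if (rspec$intercept) "Intercept", rspec$terms)
}

# Design matrix for a regression spec: one column per coefficient; the
# conflict column (if any) is supplied by the caller.
build_design_matrix <- function(rspec, data, conflict = NULL) {
  n <- if (!is.null(data) && nrow(data) > 0) nrow(data) else length(conflict)
  cols <- lapply(rspec$terms, function(term) {
    comps <- strsplit(term, ":", fixed = TRUE)[[1]]
    val <- rep(1, n)
    for (cmp in comps) {
      if (cmp == "conflict") {
        if (is.null(conflict))
          abort_config("formula uses 'conflict' but no conflict series was supplied")
        val <- val * conflict
      } else {
        val <- val * data[[cmp]]
      }
    }
    val
  })
  X <- do.call(cbind, c(if (rspec$intercept) list(rep(1, n)), cols))
  colnames(X) <- regression_coef_names(rspec)
  X
}

#' Latent trial-wise conflict series
#'
#' Conflict is high when the two options have similar learned values. The
#' default functional form is the reciprocal of the absolute difference in
#' expected values with a small positive floor,
#' `1 / (|q_upper - q_lower| + epsilon)`; the alternative `"negation"` form
#' is `-|q_upper - q_lower|`. Before entering a regression the series is
#' standardized (zero mean, unit SD) within subject; a zero-variance series
#' standardizes to all-zeros rather than erroring, which keeps degenerate
#' early-learning blocks estimable.
#'
#' @param trajectory A `q_trajectory` (or any list/data frame with `q_upper`
#'   and `q_lower`).
#' @param epsilon Positive floor added to the absolute value difference
#'   (reciprocal form only).
#' @param form `"reciprocal"` (default) or `"negation"`.
#' @param standardize Standardize to zero mean and unit SD.
#' @return Numeric vector of per-trial conflict values.
#' @export
conflict_series <- function(trajectory, epsilon = 0.01,
                            form = c("reciprocal", "negation"),
                            standardize = TRUE) {
  form <- match.arg(form)
  if (epsilon <= 0) abort_domain("epsilon must be > 0")
  qd <- abs(trajectory$q_upper - trajectory$q_lower)
  raw <- if (form == "reciprocal") 1 / (qd + epsilon) else -qd
  if (!standardize) return(raw)
  standardize_zero_safe(raw)
}

standardize_zero_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Evaluate a regressed parameter at the trial level
#'
#' Applies a fitted (or hypothesised) set of regression coefficients to
#' trial-wise covariates, with the link implied by the target parameter:
#' identity for `a` and `t` (with `a` floored at a small positive bound),
#' inverse logit for `z` and `alpha`, and for `v` the drift is
#' `qdiff * (linear predictor)` — the Q-value difference modulated by an
#' intercept scaling parameter plus covariate slopes.
#'
#' @param rspec A `regression_spec` from [parse_formula()].
#' @param coefficients Named vector of coefficients (names `Intercept` plus
#'   the spec's terms).
#' @param data Data frame holding the covariate columns.
#' @param conflict Optional per-trial conflict series (required when the
#'   formula uses `conflict`).
#' @param qdiff Per-trial Q-value differences (required for target `v`).
#' @param a_floor Positive floor for the threshold link.
#' @return Per-trial parameter values.
#' @export
evaluate_trial_parameter <- function(rspec, coefficients, data,
                                     conflict = NULL, qdiff = NULL,
                                     a_floor = 1e-3) {
  X <- build_design_matrix(rspec, data, conflict)
  want <- colnames(X)
  if (!all(want %in% names(coefficients)))
    abort_config(sprintf("missing coefficient(s): %s",
                         paste(setdiff(want, names(coefficients)), collapse = ", ")))
  lp <- as.numeric(X %*% coefficients[want])
  switch(rspec$target,
    a = pmax(lp, a_floor),
    t = lp,
    z = invlogit(lp),
    alpha = invlogit(lp),
    v = {
      if (is.null(qdiff)) abort_config("qdiff required for target 'v'")
      qdiff * lp
    })
}
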