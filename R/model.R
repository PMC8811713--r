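# Model specification and construction of the hierarchical parameter graph:
# group mean/SD nodes -> subject nodes -> (optionally regression-modulated)
# trial-level DDM parameters -> RLDDM likelihood.

#' Specify an RLDDM (or softmax-RL) model
#'
#' The default model estimates decision threshold `a`, drift scaling `v`,
#' non-decision time `t` and learning rate `alpha`, each with a group mean,
#' a group SD and subject-level values; the starting point is fixed at 0.5.
#'
#' @param include Optional parameters to add: any of `"z"` (starting point),
#'   `"sv"`, `"st"`, `"sz"` (between-trial variabilities; estimated as
#'   group-only parameters).
#' @param dual Estimate separate learning rates for positive and negative
#'   reward prediction errors.
#' @param depends_on Named list mapping a parameter (`a`, `v`, `t`, `z`) to a
#'   condition column (normally `"split_by"`); one group-level family is
#'   created per condition.
#' @param regressions Character vector of trial-wise regression formulas
#'   (see [parse_formula()]), e.g. `"a ~ neural"`. A parameter cannot be both
#'   split by condition and regressed.
#' @param choice_rule `"rlddm"` (wfpt likelihood of choice and RT) or
#'   `"softmax"` (choice-only model; drops `a`, `t`, `z` and uses `v` as the
#'   softmax inverse temperature).
#' @param conflict_form,conflict_epsilon Functional form of the latent
#'   conflict regressor, see [conflict_series()].
#' @return A `model_spec`.
#' @export
model_spec <- function(include = character(), dual = FALSE,
                       depends_on = list(), regressions = character(),
                       choice_rule = c("rlddm", "softmax"),
                       conflict_form = c("reciprocal", "negation"),
                       conflict_epsilon = 0.01) {
  choice_rule <- match.arg(choice_rule)
  conflict_form <- match.arg(conflict_form)
  bad <- setdiff(include, c("z", "sv", "st", "sz"))
  if (length(bad) > 0)
    abort_config(sprintf("unknown include entries: %s", paste(bad, collapse = ", ")))
  if (choice_rule == "softmax" &&
      (length(include) > 0 || length(regressions) > 0))
    abort_config("the softmax choice rule supports neither DDM extras nor regressions")
  structure(list(include = include, dual = dual, depends_on = depends_on,
                 regressions = regressions, choice_rule = choice_rule,
                 conflict_form = conflict_form,
                 conflict_epsilon = conflict_epsilon),
            class = "model_spec")
}

#' Read a model specification from a YAML or JSON document
#'
#' The document mirrors [model_spec()]'s arguments (`include`, `dual`,
#' `depends_on`, `regressions`, `choice_rule`, `conflict_form`,
#' `conflict_epsilon`); absent fields take their defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `model_spec`.
#' @export
read_model_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- c("include", "dual", "depends_on", "regressions", "choice_rule",
               "conflict_form", "conflict_epsilon")
  bad <- setdiff(names(doc), allowed)
  if (length(bad) > 0)
    abort_config(sprintf("unknown model-spec field(s): %s", paste(bad, collapse = ", ")))
  do.call(model_spec, doc)
}

base_params_for <- function(spec) {
  if (spec$choice_rule == "softmax") {
    c("v", "alpha", if (spec$dual) "alpha_neg")
  } else {
    c("a", "v", "t", "alpha", if (spec$dual) "alpha_neg",
      if ("z" %in% spec$include) "z")
  }
}

#' Build the hierarchical model graph
#'
#' Constructs the directed acyclic parameter graph for a dataset and a
#' [model_spec()]: per parameter family a group-mean node, a group-SD node
#' and one node per subject (on the unconstrained scale for transformed
#' parameters), plus single group-only nodes for between-trial
#' variabilities. Regression formulas replace a parameter's single family by
#' one family per coefficient (intercept and slopes).
#'
#' @param table A `trial_table`, or `NULL` for a prior-only model (then
#'   `subjects` must be given); the likelihood of a prior-only model is
#'   identically zero, so sampling it reproduces the priors.
#' @param spec A `model_spec`.
#' @param priors Prior structure, see [default_priors()].
#' @param subjects Subject ids for a prior-only model.
#' @return An `rlddm_model` object; pass to [sample_posterior()].
#' @examples
#' d <- simulate_rlddm_dataset(3, pst_schedule(15), seed = 1)
#' m <- build_model(d)
#' m$state_names
#' @export
build_model <- function(table, spec = model_spec(), priors = default_priors(),
                        subjects = NULL) {
  if (!inherits(spec, "model_spec")) abort_config("spec must be a model_spec")
  prior_only <- is.null(table)
  if (prior_only) {
    if (is.null(subjects)) abort_config("prior-only model needs explicit subjects")
  } else {
    if (!inherits(table, "trial_table"))
      table <- validate_trials(table, require_rt = spec$choice_rule == "rlddm")
    if (spec$choice_rule == "rlddm" && !isTRUE(attr(table, "has_rt")))
      abort_config("the RLDDM likelihood requires response times; use choice_rule = 'softmax'")
    subjects <- sort(unique(table$subj_idx))
  }

  params <- base_params_for(spec)
  rspecs <- lapply(spec$regressions, function(f)
    if (inherits(f, "regression_spec")) f else parse_formula(f, names(table)))
  reg_targets <- vapply(rspecs, function(r) r$target, character(1))
  if (anyDuplicated(reg_targets))
    abort_config("at most one regression formula per parameter")
  if (length(intersect(reg_targets, names(spec$depends_on))) > 0)
    abort_config(sprintf(
      "parameter(s) %s appear in both depends_on and a regression",
      paste(intersect(reg_targets, names(spec$depends_on)), collapse = ", ")))
  if ("alpha" %in% c(reg_targets, names(spec$depends_on)) ||
      "alpha_neg" %in% c(reg_targets, names(spec$depends_on)))
    abort_config("condition splits / regressions on the learning rate are not supported")
  bad_dep <- setdiff(names(spec$depends_on), params)
  if (length(bad_dep) > 0)
    abort_config(sprintf("depends_on targets not in the model: %s",
                         paste(bad_dep, collapse = ", ")))
  bad_reg <- setdiff(reg_targets, params)
  if (length(bad_reg) > 0)
    abort_config(sprintf("regression targets not in the model: %s",
                         paste(bad_reg, collapse = ", ")))
  if (length(rspecs) > 0 && !"alpha" %in% params)
    abort_config("regression models must include the learning rate")
  if (!prior_only) {
    for (r in rspecs) {
      if (length(r$terms) > 0) validate_regressor_columns(table, r$terms)
    }
    for (p in names(spec$depends_on)) {
      col <- spec$depends_on[[p]]
      if (!col %in% names(table))
        abort_config(sprintf("depends_on column '%s' not found", col))
    }
  }

  # --- parameter families ----------------------------------------------
  families <- list()
  pf <- list()  # per-parameter resolution plan
  add_family <- function(fam) families[[length(families) + 1]] <<- fam
  for (p in params) {
    pr <- priors[[p]]
    if (p %in% names(spec$depends_on)) {
      col <- spec$depends_on[[p]]
      levels <- if (prior_only) abort_config("depends_on needs data") else
        as.character(sort(unique(table[[col]])))
      fam_names <- sprintf("%s(%s)", p, levels)
      for (i in seq_along(levels)) {
        add_family(list(name = fam_names[i], param = p, kind = "base",
                        cond = levels[i], subj_dist = pr$subj,
                        transform = pr$transform,
                        mu_prior = pr$mu, sd_prior = pr$sd))
      }
      pf[[p]] <- list(type = "cond", col = col, levels = levels,
                      families = fam_names)
    } else if (p %in% reg_targets) {
      rspec <- rspecs[[match(p, reg_targets)]]
      coefs <- regression_coef_names(rspec)
      fam_names <- paste0(p, "_", coefs)
      for (i in seq_along(coefs)) {
        is_int <- coefs[i] == "Intercept"
        add_family(list(name = fam_names[i], param = p, kind = "coef",
                        cond = NA, term = coefs[i],
                        subj_dist = if (is_int) pr$subj else "normal",
                        transform = "identity",
                        mu_prior = if (is_int) pr$mu else priors$slope$mu,
                        sd_prior = pr$sd))
      }
      pf[[p]] <- list(type = "reg", rspec = rspec, families = fam_names,
                      uses_conflict = any(grepl("conflict",
                        unlist(strsplit(rspec$terms, ":", fixed = TRUE)))))
    } else {
      add_family(list(name = p, param = p, kind = "base", cond = NA,
                      subj_dist = pr$subj, transform = pr$transform,
                      mu_prior = pr$mu, sd_prior = pr$sd))
      pf[[p]] <- list(type = "single", families = p)
    }
  }
  var_params <- intersect(spec$include, c("sv", "st", "sz"))

  # --- state vector layout ---------------------------------------------
  state_names <- character(0)
  ix <- list()
  for (fam in families) {
    mu_name <- fam$name
    sd_name <- paste0(fam$name, "_std")
    subj_names <- sprintf("%s_subj.%s", fam$name, subjects)
    ix[[fam$name]] <- list(
      mu = length(state_names) + 1L,
      sd = length(state_names) + 2L,
      subj = length(state_names) + 2L + seq_along(subjects))
    state_names <- c(state_names, mu_name, sd_name, subj_names)
  }
  for (vp in var_params) {
    ix[[vp]] <- list(mu = length(state_names) + 1L)
    state_names <- c(state_names, vp)
  }

  # --- per-subject data ------------------------------------------------
  sdata <- list()
  if (!prior_only) {
    reg_cols <- unique(setdiff(
      unlist(lapply(rspecs, function(r)
        unlist(strsplit(r$terms, ":", fixed = TRUE)))), "conflict"))
    for (j in seq_along(subjects)) {
      rows <- table$subj_idx == subjects[j]
      sub <- table[rows, , drop = FALSE]
      sd_j <- list(
        response = as.integer(sub$response),
        feedback = as.numeric(sub$feedback),
        block = match(as.character(sub$split_by), unique(as.character(sub$split_by))),
        q_init = as.numeric(sub$q_init),
        n = nrow(sub),
        covars = if (length(reg_cols) > 0)
          as.data.frame(sub[, reg_cols, drop = FALSE]) else NULL)
      if (spec$choice_rule == "rlddm") {
        sd_j$rt <- as.numeric(sub$rt)
        sd_j$min_rt <- min(sd_j$rt)
      }
      for (p in names(pf)) {
        plan <- pf[[p]]
        if (plan$type == "cond")
          sd_j[[paste0("cond_", p)]] <-
            match(as.character(sub[[plan$col]]), plan$levels)
      }
      sdata[[j]] <- sd_j
    }
  }

  transformed <- unlist(lapply(families, function(fam) {
    if (fam$transform == "invlogit")
      state_names[c(ix[[fam$name]]$mu, ix[[fam$name]]$subj)]
  }))
  fam_transform <- vapply(families, `[[`, "", "transform")
  names(fam_transform) <- vapply(families, `[[`, "", "name")
  uses_conflict <- any(vapply(pf, function(p) isTRUE(p$uses_conflict), logical(1)))

  structure(list(table = if (prior_only) NULL else table, spec = spec,
                 priors = priors, subjects = subjects, families = families,
                 var_params = var_params, pf = pf, ix = ix,
                 state_names = state_names, sdata = sdata,
                 transformed = transformed %||% character(0),
                 fam_transform = fam_transform,
                 uses_conflict = uses_conflict,
                 prior_only = prior_only),
            class = "rlddm_model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.rlddm_model <- function(x, ...) {
  cat(sprintf("rlddm_model (%s): %d subject(s), %d free parameters\n",
              x$spec$choice_rule, length(x$subjects), length(x$state_names)))
  cat("families:", paste(vapply(x$families, `[[`, "", "name"), collapse = ", "),
      "\n")
  if (length(x$var_params) > 0)
    cat("group-only:", paste(x$var_params, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Likelihood assembly: resolve the per-trial DDM parameters for one subject
# from the current state vector and call the C++ block likelihood.

# Per-trial (or scalar) value of parameter p for subject j.
resolve_param <- function(model, state, j, p, conflict_cache) {
  plan <- model$pf[[p]]
  sd_j <- model$sdata[[j]]
  if (plan$type == "single") {
    val <- state[model$ix[[plan$families]]$subj[j]]
    if (model$fam_transform[[plan$families]] == "invlogit") val <- invlogit(val)
    val
  } else if (plan$type == "cond") {
    vals <- vapply(plan$families, function(f) state[model$ix[[f]]$subj[j]],
                   numeric(1))
    if (model$fam_transform[[plan$families[1]]] == "invlogit")
      vals <- invlogit(vals)
    vals[sd_j[[paste0("cond_", p)]]]
  } else {  # regression: lp is the per-trial linear predictor
    coefs <- vapply(plan$families, function(f) state[model$ix[[f]]$subj[j]],
                    numeric(1))
    names(coefs) <- regression_coef_names(plan$rspec)
    conf <- if (plan$uses_conflict) conflict_cache$get() else NULL
    X <- build_design_matrix(plan$rspec, sd_j$covars, conf)
    as.numeric(X %*% coefs)
  }
}

# Standardized conflict series across all of subject j's trials for the
# current learning rate (lazy, computed at most once per likelihood call).
make_conflict_cache <- function(model, sd_j, alpha, alpha_neg, dual) {
  env <- new.env(parent = emptyenv())
  env$val <- NULL
  list(get = function() {
    if (is.null(env$val)) {
      qd <- numeric(sd_j$n)
      for (b in unique(sd_j$block)) {
        idx <- which(sd_j$block == b)
        m <- q_trajectory_cpp(sd_j$response[idx], sd_j$feedback[idx],
                              sd_j$q_init[idx[1]], alpha,
                              if (dual) alpha_neg else alpha, dual)
        qd[idx] <- abs(m[, 1] - m[, 2])
      }
      raw <- if (model$spec$conflict_form == "reciprocal")
        1 / (qd + model$spec$conflict_epsilon) else -qd
      env$val <- standardize_zero_safe(raw)
    }
    env$val
  })
}

# Log-likelihood of subject j's trials under the current state.
subject_loglik <- function(model, state, j) {
  if (model$prior_only) return(0)
  sd_j <- model$sdata[[j]]
  spec <- model$spec
  alpha <- invlogit(state[model$ix[["alpha"]]$subj[j]])
  alpha_neg <- if (spec$dual)
    invlogit(state[model$ix[["alpha_neg"]]$subj[j]]) else alpha
  cc <- if (model$uses_conflict)
    make_conflict_cache(model, sd_j, alpha, alpha_neg, spec$dual) else NULL

  if (spec$choice_rule == "softmax") {
    beta <- resolve_param(model, state, j, "v", cc)
    if (any(beta < 0)) return(-Inf)
    return(rl_softmax_block_loglik_cpp(
      sd_j$response, sd_j$feedback, sd_j$block, sd_j$q_init,
      as.numeric(beta), alpha, alpha_neg, spec$dual))
  }

  a <- resolve_param(model, state, j, "a", cc)
  v <- resolve_param(model, state, j, "v", cc)
  t <- resolve_param(model, state, j, "t", cc)
  z <- if ("z" %in% names(model$pf)) {
    zl <- resolve_param(model, state, j, "z", cc)
    if (model$pf$z$type == "reg") invlogit(zl) else zl
  } else 0.5
  sv <- if ("sv" %in% model$var_params) state[model$ix$sv$mu] else 0
  st <- if ("st" %in% model$var_params) state[model$ix$st$mu] else 0
  sz <- if ("sz" %in% model$var_params) state[model$ix$sz$mu] else 0
  if (sv < 0 || st < 0 || sz < 0 || sz >= 1) return(-Inf)
  if (st > 0 && any(t - st / 2 < 0)) return(-Inf)
  if (sz > 0 && any(z - sz / 2 <= 0 | z + sz / 2 >= 1)) return(-Inf)
  rlddm_block_loglik_cpp(
    sd_j$rt, sd_j$response, sd_j$feedback, sd_j$block, sd_j$q_init,
    as.numeric(a), as.numeric(v), as.numeric(t), as.numeric(z),
    alpha, alpha_neg, spec$dual, sv, st, sz, 1e-4, 1e-3)
}

total_loglik <- function(model, state) {
  if (model$prior_only) return(0)
  sum(vapply(seq_along(model$subjects),
             function(j) subject_loglik(model, state, j), numeric(1)))
}
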