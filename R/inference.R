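## Mixed-effects inference on attendance and hatching success.
##
## Models are fitted by maximum likelihood with lme4. Uncertainty is
## summarised by posterior simulation under a flat prior: parameter
## vectors drawn from the multivariate normal sampling distribution of
## the ML fit, reported as medians and 2.5/97.5 percentiles (the
## Bayesian 95% credible interval of the simulated posterior).

#' Specify a mixed model
#'
#' @param response response column name
#' @param fixed character vector of fixed-effect terms (interactions
#'   via `*` / `:` welcome)
#' @param random character vector of lme4 random-effect terms, e.g.
#'   `"(1 + day_fraction | nest_type)"`
#' @param family `"gaussian"` or `"binomial"` (logit link)
#' @return list of class `unicub_model_spec`
#' @export
model_spec <- function(response, fixed, random,
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  sp <- list(response = response, fixed = fixed, random = random,
             family = family)
  class(sp) <- "unicub_model_spec"
  sp
}

#' Preset model specifications
#'
#' Four presets mirror the study design:
#' * `daily`: daily attendance ~ day-in-period x incubation type
#'   (3 levels), random intercepts for nest and species each crossed
#'   with the 2-level biparental/uniparental factor, day-in-period as a
#'   random slope.
#' * `hourly`: hourly attendance ~ (sine + cosine) x incubation type,
#'   same random intercepts, time-of-day (sine + cosine) as random
#'   slopes.
#' * `sex-daily` / `sex-hourly`: uniparental records only, sex replaces
#'   incubation type, plain nest and species random intercepts.
#'
#' @param name one of `"daily"`, `"hourly"`, `"sex-daily"`,
#'   `"sex-hourly"`
#' @param correlated_slopes keep random slopes correlated with their
#'   intercepts (default TRUE)?
#' @return a [model_spec()]
#' @export
preset_model_spec <- function(name = c("daily", "hourly", "sex-daily",
                                       "sex-hourly"),
                              correlated_slopes = TRUE) {
  name <- match.arg(name)
  rs <- function(slope, grp) {
    if (correlated_slopes) sprintf("(1 + %s | %s)", slope, grp)
    else sprintf("(1 | %s) + (0 + %s | %s)", grp, slope, grp)
  }
  switch(name,
    daily = model_spec("attendance", "day_fraction * inc_type",
                       c(rs("day_fraction", "nest_type"),
                         rs("day_fraction", "species_type"))),
    hourly = model_spec("attendance", "(sine + cosine) * inc_type",
                        c(rs("sine + cosine", "nest_type"),
                          rs("sine + cosine", "species_type"))),
    `sex-daily` = model_spec("attendance", "day_fraction * sex",
                             c(rs("day_fraction", "nest_id"),
                               rs("day_fraction", "species"))),
    `sex-hourly` = model_spec("attendance", "(sine + cosine) * sex",
                              c(rs("sine + cosine", "nest_id"),
                                rs("sine + cosine", "species"))))
}

#' Add the composite nest x type and species x type grouping factors
#'
#' The random-intercept structure places nest and species "in
#' interaction with incubation type" collapsed to two levels
#' (biparental vs uniparental); this derives `type2`, `nest_type` and
#' `species_type` columns from an attendance-record table.
#'
#' @param records attendance records with `nest_id`, `species`,
#'   `inc_type`
#' @return the table with the grouping columns added (copy)
#' @export
add_grouping_factors <- function(records) {
  rec <- copy(as.data.table(records))
  rec[, type2 := fifelse(inc_type == "biparental", "biparental", "uniparental")]
  rec[, nest_type := paste(nest_id, type2, sep = ":")]
  rec[, species_type := paste(species, type2, sep = ":")]
  rec[]
}

#' Fit a mixed-effects model
#'
#' Maximum-likelihood fit (lmer with `REML = FALSE`, or glmer for the
#' binomial family). Degenerate designs (a grouping factor with fewer
#' than two levels) raise an informative error; non-convergence is
#' flagged on the result, never silent.
#'
#' @param records data with all referenced columns
#' @param spec a [model_spec()] or preset name
#' @return list of class `unicub_fit`: `fit` (merMod), `spec`,
#'   `n_obs`, `converged`, `fixef` table
#' @export
fit_mixed_model <- function(records, spec) {
  if (is.character(spec)) spec <- preset_model_spec(spec)
  stopifnot(inherits(spec, "unicub_model_spec"))
  rec <- as.data.table(records)
  fml <- as.formula(paste(spec$response, "~",
                          paste(spec$fixed, collapse = " + "), "+",
                          paste(spec$random, collapse = " + ")))
  grp_vars <- unique(unlist(lapply(spec$random, function(r) {
    g <- sub("^.*\\|\\s*", "", gsub("[()]", "", r))
    trimws(g)
  })))
  missing_cols <- setdiff(grp_vars, names(rec))
  if (length(missing_cols))
    stop("grouping column(s) absent from data: ",
         paste(missing_cols, collapse = ", "),
         " (see add_grouping_factors())")
  for (g in grp_vars) {
    nl <- length(unique(rec[[g]]))
    if (nl < 2)
      stop("degenerate design: grouping factor '", g, "' has ", nl,
           " level(s); at least 2 are required")
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    if (spec$family == "gaussian")
      lme4::lmer(fml, data = rec, REML = FALSE)
    else
      lme4::glmer(fml, data = rec, family = stats::binomial()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {   # e.g. lme4's "boundary (singular) fit"
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    !any(grepl("converge", msgs, ignore.case = TRUE))
  fe <- lme4::fixef(fit)
  out <- list(fit = fit, spec = spec, n_obs = nrow(rec),
              converged = conv, messages = msgs,
              fixef = data.table(term = names(fe), estimate = unname(fe)))
  class(out) <- "unicub_fit"
  out
}

#' @export
#' @method print unicub_fit
print.unicub_fit <- function(x, ...) {
  cat(sprintf("<unicub_fit> %s model, n = %d, converged: %s\n",
              x$spec$family, x$n_obs, x$converged))
  print(x$fixef)
  invisible(x)
}

#' Simulation-based posterior summaries
#'
#' Draws `n_draws` fixed-effect vectors from the multivariate normal
#' sampling distribution of the ML fit (flat prior) and reports the
#' median and the 2.5/97.5 percentiles per term. Deterministic under
#' `seed`.
#'
#' @param fit a `unicub_fit` (or merMod)
#' @param n_draws number of simulated parameter vectors (default 5000)
#' @param seed RNG seed
#' @return data.table: `term`, `median`, `ci_low`, `ci_high`; with
#'   attributes `n_draws` and `seed`
#' @export
posterior_summaries <- function(fit, n_draws = 5000, seed = 1) {
  if (inherits(fit, "unicub_fit")) fit <- fit$fit
  if (n_draws < 100)
    warning("n_draws < 100 gives unstable credible intervals")
  set.seed(seed)
  if (is.list(fit) && !is.null(fit$beta)) {   # bare (beta, V) pair
    beta <- fit$beta
    V <- as.matrix(fit$V)
  } else {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  }
  draws <- MASS::mvrnorm(n_draws, mu = beta, Sigma = V)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, names(beta)))
  qs <- apply(draws, 2, quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  out <- data.table(term = colnames(draws), median = qs[1, ],
                    ci_low = qs[2, ], ci_high = qs[3, ])
  setattr(out, "n_draws", n_draws)
  setattr(out, "seed", seed)
  out[]
}

#' Variance components as percentage shares
#'
#' Each random-effect variance (per grouping factor and term) plus the
#' residual is expressed as a percentage of their sum; shares total
#' 100.
#'
#' @param fit a `unicub_fit` or merMod (gaussian)
#' @return data.table: `component`, `variance`, `share` (%)
#' @export
variance_components <- function(fit) {
  if (inherits(fit, "unicub_fit")) fit <- fit$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[is.na(vc$var2), ]   # drop covariance rows
  comp <- ifelse(is.na(vc$var1) | vc$var1 == "(Intercept)", vc$grp,
                 paste(vc$grp, vc$var1, sep = "."))
  v <- vc$vcov
  if (sum(v) <= 0) stop("all variance components are zero: shares undefined")
  data.table(component = comp, variance = v, share = 100 * v / sum(v))
}

#' Fit the nest-success model
#'
#' Binomial (logit) mixed model of hatching success for uniparentally
#' incubated nests: success ~ start of the uniparental phase within the
#' incubation period (%) + duration of uniparental incubation (days) +
#' median daily attendance during the phase (%), with species as a
#' random intercept. Also reports pairwise predictor correlations
#' (Pearson and Spearman) and flags (quasi-)complete separation.
#'
#' @param nest_table one row per uniparental nest: `success` (0/1),
#'   `start_fraction`, `duration_days`, `median_attendance`, `species`
#' @param n_draws,seed passed to [posterior_summaries()]
#' @return list: `fit` (unicub_fit), `posterior`, `correlations`
#'   (data.table of pairwise |r|), `separation` (logical flag),
#'   `separation_note`
#' @export
fit_success_model <- function(nest_table, n_draws = 5000, seed = 1) {
  nt <- as.data.table(nest_table)
  need <- c("success", "start_fraction", "duration_days",
            "median_attendance", "species")
  miss <- setdiff(need, names(nt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  nt <- nt[complete.cases(nt[, ..need])]
  sep_note <- NULL
  if (length(unique(nt$success)) < 2) {
    sep_note <- "all outcomes identical: coefficients are not identifiable"
  }
  spec <- model_spec("success",
                     c("start_fraction", "duration_days", "median_attendance"),
                     "(1 | species)", family = "binomial")
  if (!is.null(sep_note)) {
    return(list(fit = NULL, posterior = NULL,
                correlations = .predictor_correlations(nt),
                separation = TRUE, separation_note = sep_note))
  }
  fit <- fit_mixed_model(nt, spec)
  pr <- stats::fitted(fit$fit)
  separated <- any(abs(fit$fixef$estimate[-1]) > 15) ||
    (all(pr[nt$success == 1] > 1 - 1e-8) && all(pr[nt$success == 0] < 1e-8))
  if (separated)
    sep_note <- paste("(quasi-)complete separation detected; estimates are",
                      "unstable - consider pooling predictors or penalised",
                      "likelihood")
  post <- posterior_summaries(fit, n_draws = n_draws, seed = seed)
  list(fit = fit, posterior = post,
       correlations = .predictor_correlations(nt),
       separation = separated, separation_note = sep_note)
}

.predictor_correlations <- function(nt) {
  preds <- c("start_fraction", "duration_days", "median_attendance")
  combs <- utils::combn(preds, 2)
  rbindlist(lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    data.table(pair = paste(a, b, sep = " ~ "),
               pearson = cor(nt[[a]], nt[[b]], method = "pearson"),
               spearman = cor(nt[[a]], nt[[b]], method = "spearman"))
  }))
}
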