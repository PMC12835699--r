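# Conditional-probability queries on a fitted CLG network: median-threshold
# events on continuous variables (or level equality on discrete ones),
# estimated by Monte-Carlo ancestral sampling with rejection conditioning.

#' Median (and modal) reference points of a dataset
#'
#' Per continuous variable the sample median (mean of the middle two values
#' for even n); per discrete variable the modal level, recorded as the
#' reference for "=" queries (ties resolved toward the earlier level).
#'
#' @param data complete data frame.
#' @param spec matching [variable_spec()].
#' @return named list: numeric medians for continuous variables, character
#'   modal levels for discrete ones.
#' @export
median_thresholds <- function(data, spec) {
  data <- conform_data(data, spec)
  if (anyNA(data)) stop("data must be complete")
  out <- list()
  for (i in seq_len(nrow(spec))) {
    v <- spec$name[i]
    out[[v]] <- if (spec$kind[i] == "continuous")
      stats::median(data[[v]])
    else {
      tab <- table(data[[v]])
      names(tab)[which.max(tab)]
    }
  }
  out
}

#' A median-threshold query specification
#'
#' @param variable variable name the event is about.
#' @param relation `"<"` or `">"` (continuous, relative to `reference`), or
#'   `"="` (discrete level equality).
#' @param reference the median value (continuous) or level (discrete).
#' @return a list of class `clg_query_clause`.
#' @export
query_clause <- function(variable, relation = c("<", ">", "="), reference) {
  relation <- match.arg(relation)
  structure(list(variable = variable, relation = relation,
                 reference = reference), class = "clg_query_clause")
}

clause_mask <- function(clause, samples) {
  x <- samples[[clause$variable]]
  switch(clause$relation,
         "<" = x < clause$reference,
         ">" = x > clause$reference,
         "=" = as.character(x) == as.character(clause$reference),
         stop("unknown relation"))
}

#' Monte-Carlo conditional-probability query
#'
#' Draws `n_samples` ancestral samples from the fitted network, rejects those
#' violating the evidence clauses, and reports the fraction of survivors
#' satisfying the event, with the binomial Monte-Carlo standard error
#' `sqrt(p (1 - p) / n_effective)`. Ties at a continuous threshold satisfy
#' neither `<` nor `>`.
#'
#' @param net a fitted network: list with `dag`, `params`, `spec` (a
#'   `clg_truth` or the output of [fit_parameters()] wrapped with its dag and
#'   spec).
#' @param event a [query_clause()].
#' @param evidence list of [query_clause()]s (may be empty); must not
#'   mention the event variable.
#' @param n_samples Monte-Carlo sample count (>= 1000).
#' @param seed integer seed.
#' @return list of class `clg_query_result`: `probability`,
#'   `mc_standard_error`, `n_effective`.
#' @export
conditional_query <- function(net, event, evidence = list(),
                              n_samples = 1e6, seed = 1L) {
  stopifnot(n_samples >= 1000)
  for (cl in evidence)
    if (cl$variable == event$variable)
      stop("event variable appears in the evidence")
  samples <- sample_dataset(net, n_samples, seed = seed)
  keep <- rep(TRUE, n_samples)
  for (cl in evidence) keep <- keep & clause_mask(cl, samples)
  n_eff <- sum(keep)
  if (n_eff == 0)
    stop("evidence never satisfied (n_effective = 0); ",
         "incompatible evidence or too few samples")
  p <- mean(clause_mask(event, samples)[keep])
  structure(list(probability = p,
                 mc_standard_error = sqrt(p * (1 - p) / n_eff),
                 n_effective = n_eff),
            class = "clg_query_result")
}

#' @export
print.clg_query_result <- function(x, ...) {
  cat(sprintf("P = %.4f (MC se %.4f, n_eff %d)\n",
              x$probability, x$mc_standard_error, x$n_effective))
  invisible(x)
}

#' Battery of median-split conditional queries
#'
#' For each row of `pairs`, estimates
#' `P(variable2 sign2 median | variable1 sign1 median)` under the fitted
#' network, using the median (continuous) or modal-level (discrete, `"="`)
#' references computed from `data`. All queries share one set of
#' Monte-Carlo samples.
#'
#' @inheritParams conditional_query
#' @param data the analysis dataset the medians are computed from.
#' @param pairs data frame with columns `variable1`, `sign1`, `variable2`,
#'   `sign2` (signs among `<`, `>`, `=`).
#' @return data frame: the four input columns plus `probability`,
#'   `mc_standard_error`, `n_effective`.
#' @export
query_battery <- function(net, data, pairs, n_samples = 1e6, seed = 1L) {
  spec <- net$spec
  stopifnot(all(c(pairs$variable1, pairs$variable2) %in% spec$name))
  if (any(pairs$variable1 == pairs$variable2))
    stop("self-pair in the query battery")
  thr <- median_thresholds(data, spec)
  samples <- sample_dataset(net, n_samples, seed = seed)
  out <- pairs
  out$probability <- out$mc_standard_error <- NA_real_
  out$n_effective <- NA_integer_
  for (i in seq_len(nrow(pairs))) {
    ev <- query_clause(pairs$variable1[i], pairs$sign1[i],
                       thr[[pairs$variable1[i]]])
    qc <- query_clause(pairs$variable2[i], pairs$sign2[i],
                       thr[[pairs$variable2[i]]])
    keep <- clause_mask(ev, samples)
    n_eff <- sum(keep)
    if (n_eff == 0) stop("evidence never satisfied for row ", i)
    p <- mean(clause_mask(qc, samples)[keep])
    out$probability[i] <- p
    out$mc_standard_error[i] <- sqrt(p * (1 - p) / n_eff)
    out$n_effective[i] <- n_eff
  }
  out
}

#' Default CATIE-like query battery
#'
#' The roster of median-split pairs reported for the cognitive subscales and
#' the parents of quality of life: each remaining MATRICS domain given low
#' processing speed, and each QOL parent paired with QOL.
#'
#' @return a `pairs` data frame for [query_battery()].
#' @export
default_query_battery <- function() {
  rbind(
    data.frame(variable1 = "matrics_speed", sign1 = "<",
               variable2 = c("matrics_memory", "matrics_reasoning",
                             "matrics_vigilance", "matrics_verbal"),
               sign2 = "<", stringsAsFactors = FALSE),
    data.frame(variable1 = c("panss_negative", "matrics_speed", "cdss",
                             "dai", "cgi_severity"),
               sign1 = c(">", "<", ">", ">", ">"),
               variable2 = "qol",
               sign2 = c("<", ">", "<", ">", "<"),
               stringsAsFactors = FALSE),
    data.frame(variable1 = "employment", sign1 = "=",
               variable2 = "qol", sign2 = ">", stringsAsFactors = FALSE)
  )
}
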