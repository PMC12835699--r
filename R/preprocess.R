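# Preprocessing: row-level missingness filtering, iterative random-forest
# (missForest-style) imputation of mixed data, age categorization, and
# standardization of cognitive scores.

#' Remove rows with excessive missingness
#'
#' Drops exactly the rows whose fraction of missing cells is strictly greater
#' than `threshold` (a row with exactly the threshold fraction is retained);
#' surviving rows keep their original order.
#'
#' @param data a data frame.
#' @param threshold proportion in `(0, 1]`.
#' @return list: `data` (filtered), `n_removed`.
#' @export
filter_rows_by_missingness <- function(data, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- rowMeans(is.na(data))
  keep <- frac <= threshold
  if (!any(keep)) stop("all rows exceed the missingness threshold")
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(data = out, n_removed = sum(!keep))
}

#' Iterative random-forest imputation of mixed data
#'
#' The missForest scheme of Stekhoven & Buhlmann: missing cells are
#' initialized with the column mean (continuous) or mode (discrete); then,
#' looping over variables in order of increasing missingness (ties by column
#' order), each variable with missing cells is regressed on all others with a
#' random forest and its missing cells replaced by the forest's predictions.
#' Iterations stop when the iteration-over-iteration difference criterion
#' (squared-difference ratio for continuous variables, disagreement fraction
#' for discrete) increases for both variable kinds — or for the only kind
#' present — or at `max_iter`; the imputation from the last iteration before
#' the increase is returned.
#'
#' @param data data frame with missing cells.
#' @param spec matching [variable_spec()].
#' @param max_iter maximum number of sweeps (>= 1).
#' @param n_trees trees per forest (missForest's default 100).
#' @param seed integer seed; the imputation is deterministic given it.
#' @return list: `data` (complete), `report` (class `clg_imputation_report`:
#'   `cell_missing_fraction`, `n_iterations`, per-iteration difference
#'   criteria, `final_difference_continuous`, `final_difference_discrete`).
#' @export
impute_random_forest <- function(data, spec, max_iter = 10L, n_trees = 100L,
                                 seed = 1L) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  data <- conform_data(data, spec)
  na_mask <- is.na(data)
  if (any(colSums(!na_mask) == 0))
    stop("column(s) with zero observed values: ",
         paste(names(data)[colSums(!na_mask) == 0], collapse = ", "))
  miss_frac <- mean(na_mask)
  n_missing <- colSums(na_mask)

  disc <- spec$kind == "discrete"
  # initialization: mean / mode from observed cells
  imp <- data
  for (j in seq_len(ncol(imp))) {
    if (n_missing[j] == 0) next
    obs <- imp[[j]][!na_mask[, j]]
    fill <- if (disc[j]) {
      tab <- table(obs)
      factor(names(tab)[which.max(tab)], levels = levels(imp[[j]]))
    } else mean(obs)
    imp[[j]][na_mask[, j]] <- fill
  }
  if (miss_frac == 0) {
    report <- structure(list(n_rows_removed = NA_integer_,
                             cell_missing_fraction = 0, n_iterations = 1L,
                             final_difference_continuous = 0,
                             final_difference_discrete = 0,
                             history = data.frame()),
                        class = "clg_imputation_report")
    return(list(data = imp, report = report))
  }

  # sweep order: ascending missingness, ties by column order
  sweep_order <- order(n_missing, seq_along(n_missing))
  sweep_order <- sweep_order[n_missing[sweep_order] > 0]
  has_cont <- any(!disc & n_missing > 0)
  has_disc <- any(disc & n_missing > 0)

  diff_pair <- function(new, old) {
    dc <- dd <- NA_real_
    if (has_cont) {
      num <- den <- 0
      for (j in which(!disc & n_missing > 0)) {
        num <- num + sum((new[[j]] - old[[j]])^2)
        den <- den + sum(new[[j]]^2)
      }
      dc <- if (den > 0) num / den else 0
    }
    if (has_disc) {
      changed <- tot <- 0
      for (j in which(disc & n_missing > 0)) {
        m <- na_mask[, j]
        changed <- changed + sum(new[[j]][m] != old[[j]][m])
        tot <- tot + sum(m)
      }
      dd <- changed / tot
    }
    c(continuous = dc, discrete = dd)
  }

  prev <- imp
  prev_diff <- c(continuous = Inf, discrete = Inf)
  history <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new <- prev
    for (j in sweep_order) {
      v <- names(new)[j]
      m <- na_mask[, j]
      train <- new[!m, , drop = FALSE]
      fit <- ranger::ranger(
        dependent.variable.name = v, data = train,
        num.trees = n_trees,
        mtry = if (disc[j]) max(1L, floor(sqrt(ncol(new) - 1)))
               else max(1L, floor((ncol(new) - 1) / 3)),
        num.threads = 1L, seed = seed + iter * 1000L + j,
        respect.unordered.factors = "order", verbose = FALSE)
      pred <- stats::predict(fit, data = new[m, , drop = FALSE],
                             num.threads = 1L,
                             seed = seed + iter * 1000L + j)$predictions
      if (disc[j]) pred <- factor(as.character(pred),
                                  levels = levels(new[[j]]))
      new[[j]][m] <- pred
    }
    d <- diff_pair(new, prev)
    history[[iter]] <- data.frame(iteration = iter,
                                  diff_continuous = d[["continuous"]],
                                  diff_discrete = d[["discrete"]])
    worse_cont <- !has_cont || d[["continuous"]] > prev_diff[["continuous"]]
    worse_disc <- !has_disc || d[["discrete"]] > prev_diff[["discrete"]]
    if (worse_cont && worse_disc) {
      final <- prev  # last iteration before the increase
      final_diff <- prev_diff
      break
    }
    prev <- new
    prev_diff <- d
    if (iter >= max_iter) { final <- new; final_diff <- d; break }
  }
  report <- structure(
    list(n_rows_removed = NA_integer_,
         cell_missing_fraction = miss_frac,
         n_iterations = iter,
         final_difference_continuous =
           if (has_cont) unname(final_diff[["continuous"]]) else 0,
         final_difference_discrete =
           if (has_disc) unname(final_diff[["discrete"]]) else 0,
         history = do.call(rbind, history)),
    class = "clg_imputation_report")
  list(data = final, report = report)
}

#' @export
print.clg_imputation_report <- function(x, ...) {
  cat(sprintf(
    "Imputation: %.2f%% of cells missing, %d iteration(s)\n",
    100 * x$cell_missing_fraction, x$n_iterations))
  invisible(x)
}

#' Categorize age in years into three bands
#'
#' Bands `<30` (up to and including 30), `31-45`, and `>45`, applied to
#' integer-rounded years.
#'
#' @param values numeric vector of positive ages in years.
#' @param breaks the two cut ages (defaults 30 and 45).
#' @return factor with levels `c("<30", "31-45", ">45")`.
#' @export
categorize_age <- function(values, breaks = c(30, 45)) {
  if (any(values <= 0, na.rm = TRUE)) stop("ages must be positive")
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  v <- round(values)
  labs <- c(paste0("<", breaks[1]),
            paste0(breaks[1] + 1, "-", breaks[2]),
            paste0(">", breaks[2]))
  out <- ifelse(v <= breaks[1], labs[1],
                ifelse(v <= breaks[2], labs[2], labs[3]))
  factor(out, levels = labs)
}

#' Standardize continuous columns to mean 0, sd 1
#'
#' Sample standard deviation with denominator `n - 1`. Errors on a
#' zero-variance column.
#'
#' @param data a data frame.
#' @param columns names of continuous columns to standardize.
#' @return the data frame with the named columns rescaled.
#' @export
standardize_columns <- function(data, columns) {
  for (v in columns) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("column '", v, "' is not continuous")
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero-variance column '", v, "'")
    data[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}
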