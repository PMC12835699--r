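# Plain-text interchange: mixed datasets as CSV (missing cells as empty
# fields) with a companion variable-spec file, CLG parameters as JSON.

#' Bundle fitted parameters into a queryable network
#'
#' @param params a [fit_parameters()] object (carries its dag and spec).
#' @return list with `dag`, `params`, `spec` — the shape expected by
#'   [sample_dataset()] and [conditional_query()].
#' @export
clg_network <- function(params) {
  stopifnot(inherits(params, "clg_params"))
  list(dag = params$dag, params = params, spec = params$spec)
}

#' Read / write a mixed dataset as CSV
#'
#' Header row, missing cells encoded as empty fields; discrete columns are
#' restored to factors with the declared level order on read.
#'
#' @param data a data frame.
#' @param path CSV file path.
#' @param spec matching [variable_spec()].
#' @return `write_mixed_csv` returns `path` invisibly; `read_mixed_csv`
#'   returns the data frame.
#' @export
write_mixed_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_mixed_csv
#' @export
read_mixed_csv <- function(path, spec) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"),
                         check.names = FALSE)
  out <- conform_data(raw, spec)
  out
}

#' Export CLG parameters as JSON
#'
#' CPTs as nested mappings (configuration labels to level probabilities),
#' regressions as coefficient lists with residual sds.
#'
#' @param params a `clg_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  spec <- params$spec
  out <- lapply(params$nodes, function(fam) {
    cfg_names <- vapply(seq_len(
      if (fam$kind == "discrete") nrow(fam$cpt) else nrow(fam$coef)),
      function(k) {
        lab <- config_labels(spec, fam$dparents, k)
        if (length(lab)) paste(names(lab), lab, sep = "=", collapse = ",")
        else "(no discrete parents)"
      }, "")
    if (fam$kind == "discrete") {
      rows <- lapply(seq_len(nrow(fam$cpt)), function(k)
        as.list(stats::setNames(fam$cpt[k, ], colnames(fam$cpt))))
      list(kind = "discrete", parents = fam$dparents,
           cpt = stats::setNames(rows, cfg_names))
    } else {
      rows <- lapply(seq_len(nrow(fam$coef)), function(k)
        list(intercept = unname(fam$coef[k, 1]),
             slopes = as.list(stats::setNames(
               fam$coef[k, -1, drop = TRUE],
               fam$cparents)),
             residual_sd = fam$sd[k]))
      list(kind = "continuous",
           discrete_parents = fam$dparents,
           continuous_parents = fam$cparents,
           regressions = stats::setNames(rows, cfg_names))
    }
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# small stable polynomial hash of a character scalar, for provenance records
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
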