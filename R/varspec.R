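#' Declare a set of mixed-type variables
#'
#' A variable specification records, for every column of a dataset, whether it
#' is discrete (with an ordered list of levels) or continuous, its analysis
#' role, and — for discrete variables — whether the levels carry a natural
#' order (used when the variable is numerically encoded for the path model).
#'
#' @param name character vector of unique variable names.
#' @param kind character vector, each `"discrete"` or `"continuous"`.
#' @param levels list of character vectors; level roster per discrete variable
#'   (must be `NULL` for continuous variables, length >= 2 otherwise).
#' @param role character vector; one of `"demographic"`, `"clinical"`,
#'   `"cognitive"`, `"qol"` per variable.
#' @param ordered logical vector; `TRUE` for discrete variables whose levels
#'   are ordinal. Ignored for continuous variables.
#'
#' @return An object of class `clg_spec`: a data frame with one row per
#'   variable and a list column `levels`.
#' @export
variable_spec <- function(name, kind, levels = vector("list", length(name)),
                          role = rep("clinical", length(name)),
                          ordered = rep(FALSE, length(name))) {
  stopifnot(is.character(name), !anyDuplicated(name))
  kind <- match.arg(kind, c("discrete", "continuous"), several.ok = TRUE)
  if (length(kind) == 1L) kind <- rep(kind, length(name))
  role <- match.arg(role, c("demographic", "clinical", "cognitive", "qol"),
                    several.ok = TRUE)
  if (length(role) == 1L) role <- rep(role, length(name))
  stopifnot(length(kind) == length(name), length(role) == length(name),
            length(levels) == length(name), length(ordered) == length(name))
  for (i in seq_along(name)) {
    if (kind[i] == "discrete") {
      if (is.null(levels[[i]]) || length(levels[[i]]) < 2L)
        stop("discrete variable '", name[i], "' needs >= 2 levels")
      if (anyDuplicated(levels[[i]]))
        stop("duplicate levels for '", name[i], "'")
    } else if (!is.null(levels[[i]])) {
      stop("continuous variable '", name[i], "' must not declare levels")
    }
  }
  out <- data.frame(name = name, kind = kind, role = role,
                    ordered = as.logical(ordered), stringsAsFactors = FALSE)
  out$levels <- unname(levels)
  class(out) <- c("clg_spec", "data.frame")
  out
}

#' @export
print.clg_spec <- function(x, ...) {
  cat("Variable specification:", nrow(x), "variables (",
      sum(x$kind == "discrete"), "discrete,",
      sum(x$kind == "continuous"), "continuous )\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %-10s %-11s", x$name[i], x$kind[i], x$role[i]))
    if (x$kind[i] == "discrete")
      cat(" {", paste(x$levels[[i]], collapse = ", "), "}",
          if (x$ordered[i]) " (ordered)" else "", sep = "")
    cat("\n")
  }
  invisible(x)
}

spec_names <- function(spec) spec$name

is_discrete <- function(spec, v) {
  spec$kind[match(v, spec$name)] == "discrete"
}

levels_of <- function(spec, v) {
  spec$levels[[match(v, spec$name)]]
}

spec_subset <- function(spec, vars) {
  out <- spec[match(vars, spec$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clg_spec", "data.frame")
  out
}

#' Derive a variable specification from a data frame
#'
#' Factor/character columns become discrete (levels in factor order, or sorted
#' unique values for character), numeric columns continuous.
#'
#' @param data a data frame.
#' @param role role label(s) recycled across columns.
#' @return A [variable_spec()] object.
#' @export
spec_from_data <- function(data, role = "clinical") {
  stopifnot(is.data.frame(data))
  kind <- character(ncol(data))
  lv <- vector("list", ncol(data))
  for (j in seq_len(ncol(data))) {
    x <- data[[j]]
    if (is.factor(x)) {
      kind[j] <- "discrete"; lv[[j]] <- levels(x)
    } else if (is.character(x)) {
      kind[j] <- "discrete"; lv[[j]] <- sort(unique(x[!is.na(x)]))
    } else if (is.numeric(x)) {
      kind[j] <- "continuous"
    } else stop("unsupported column type: ", names(data)[j])
  }
  variable_spec(names(data), kind, lv, role = role)
}

#' Read / write a variable specification
#'
#' The on-disk format is a YAML mapping from variable name to a block with
#' `kind`, `role`, `ordered` and (for discrete variables) `levels`.
#'
#' @param spec a `clg_spec`.
#' @param path file path.
#' @return `read_var_spec` returns a `clg_spec`; `write_var_spec` returns
#'   `path` invisibly.
#' @export
write_var_spec <- function(spec, path) {
  lst <- lapply(seq_len(nrow(spec)), function(i) {
    b <- list(kind = spec$kind[i], role = spec$role[i],
              ordered = spec$ordered[i])
    if (spec$kind[i] == "discrete") b$levels <- as.list(spec$levels[[i]])
    b
  })
  names(lst) <- spec$name
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_var_spec
#' @export
read_var_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  variable_spec(
    name = names(lst),
    kind = vapply(lst, `[[`, "", "kind"),
    levels = lapply(lst, function(b) {
      if (is.null(b$levels)) NULL else unlist(b$levels)
    }),
    role = vapply(lst, `[[`, "", "role"),
    ordered = vapply(lst, function(b) isTRUE(b$ordered), NA)
  )
}

# validate a data frame against a spec; returns the data with discrete columns
# coerced to factors carrying the declared level order
conform_data <- function(data, spec) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(spec$name, names(data))
  if (length(missing_cols))
    stop("data lacks declared columns: ", paste(missing_cols, collapse = ", "))
  data <- data[spec$name]
  for (i in seq_len(nrow(spec))) {
    v <- spec$name[i]
    if (spec$kind[i] == "discrete") {
      x <- data[[v]]
      vals <- if (is.factor(x)) as.character(x) else as.character(x)
      bad <- setdiff(unique(vals[!is.na(vals)]), spec$levels[[i]])
      if (length(bad))
        stop("undeclared level(s) in '", v, "': ", paste(bad, collapse = ", "))
      data[[v]] <- factor(vals, levels = spec$levels[[i]])
    } else {
      if (!is.numeric(data[[v]]))
        data[[v]] <- as.numeric(data[[v]])
    }
  }
  data
}
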