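#' Two-way table of phenotype means
#'
#' A `phenotype_table` holds means of an observed trait (e.g. flowering time in
#' growing degree days, or yield) for genotypes (rows) grown in environments
#' (columns).  Missing cells are encoded as `NA` in the value matrix; the
#' observed mask is exactly `!is.na()`.  Every row and every column must retain
#' at least one observed cell, and all observed values must be finite.
#'
#' @param values numeric matrix, genotypes in rows and environments in columns.
#'   `NA` marks an unobserved genotype-environment combination.
#' @param genotypes,environments character vectors of unique row / column
#'   labels.  Default to the `dimnames` of `values`, or `G1..`, `E1..`.
#'
#' @return An object of class `phenotype_table`: the value matrix with
#'   genotype and environment labels as `dimnames`.
#' @seealso [read_phenotype_table()], [margins()], [is_connected()],
#'   [gei_response()]
#' @export
#' @examples
#' pt <- phenotype_table(matrix(c(1, 3, 2, NA), 2, 2))
#' summary(pt)
phenotype_table <- function(values, genotypes = NULL, environments = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  genotypes <- as.character(genotypes %||% rownames(values) %||%
    paste0("G", seq_len(nrow(values))))
  environments <- as.character(environments %||% colnames(values) %||%
    paste0("E", seq_len(ncol(values))))
  dimnames(values) <- list(genotypes, environments)
  x <- structure(values, class = c("phenotype_table", "matrix"))
  validate_phenotype_table(x)
}

validate_phenotype_table <- function(x) {
  g <- rownames(x)
  e <- colnames(x)
  if (anyDuplicated(g)) {
    stop("duplicate genotype labels: ", paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  if (anyDuplicated(e)) {
    stop("duplicate environment labels: ", paste(unique(e[duplicated(e)]), collapse = ", "))
  }
  if (any(is.infinite(x) | is.nan(x), na.rm = TRUE)) {
    stop("observed phenotype values must be finite")
  }
  obs <- !is.na(x)
  bad_g <- g[rowSums(obs) == 0]
  if (length(bad_g)) {
    stop("genotype(s) with no observed values: ", paste(bad_g, collapse = ", "))
  }
  bad_e <- e[colSums(obs) == 0]
  if (length(bad_e)) {
    stop("environment(s) with no observed values: ", paste(bad_e, collapse = ", "))
  }
  x
}

#' @export
print.phenotype_table <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "phenotype_table: %d genotypes x %d environments, %.1f%% missing\n",
    s$n_genotypes, s$n_environments, s$pct_missing
  ))
  invisible(x)
}

#' Summarize a phenotype table
#'
#' Reports the counts of genotypes and environments and the percentage of
#' missing cells, `100 * n_missing / (n_genotypes * n_environments)`, rounded
#' to one decimal.
#'
#' @param object a [phenotype_table()].
#' @param ... unused.
#' @return A list with `n_genotypes`, `n_environments`, `n_observed`,
#'   `n_missing` and `pct_missing`.
#' @export
summary.phenotype_table <- function(object, ...) {
  obs <- !is.na(object)
  n_missing <- sum(!obs)
  structure(list(
    n_genotypes = nrow(object),
    n_environments = ncol(object),
    n_observed = sum(obs),
    n_missing = n_missing,
    pct_missing = round(100 * n_missing / length(object), 1)
  ), class = "summary.phenotype_table")
}

#' @export
print.summary.phenotype_table <- function(x, ...) {
  cat(sprintf(
    "genotypes: %d\nenvironments: %d\nobserved cells: %d\nmissing: %d (%.1f%%)\n",
    x$n_genotypes, x$n_environments, x$n_observed, x$n_missing, x$pct_missing
  ))
  invisible(x)
}

# Strings accepted as "missing" in delimited input, besides an empty field.
MISSING_SENTINELS <- c("", "NA", "NaN", ".")

parse_numeric_field <- function(s, what) {
  s <- trimws(s)
  out <- rep(NA_real_, length(s))
  is_na <- s %in% MISSING_SENTINELS | is.na(s)
  v <- suppressWarnings(as.numeric(s[!is_na]))
  if (anyNA(v)) {
    bad <- s[!is_na][is.na(v)]
    stop("non-numeric ", what, " field(s): ", paste(unique(bad), collapse = ", "))
  }
  out[!is_na] <- v
  out
}

#' Read a phenotype table from delimited text
#'
#' Two layouts are supported.  *Wide*: a header row of environment labels with
#' the genotype label in the first column; empty fields (or `NA`, `NaN`, `.`)
#' are missing cells.  *Long*: three columns `genotype, environment, value`;
#' replicate records for the same (genotype, environment) pair are averaged to
#' a single mean, because the downstream methodology consumes a two-way table
#' of means.  Rows or columns with no observed value are rejected with an
#' error naming the offending label.
#'
#' @param path path to a delimited text file.
#' @param layout `"wide"` or `"long"`.
#' @param sep field separator; comma by default, tab accepted.
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path, layout = c("wide", "long"), sep = ",") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, colClasses = "character",
    check.names = FALSE, quote = "\"", comment.char = "", na.strings = NULL,
    blank.lines.skip = TRUE
  )
  if (layout == "wide") {
    env <- colnames(raw)[-1]
    if (anyDuplicated(env)) {
      stop("duplicate environment header(s): ",
        paste(unique(env[duplicated(env)]), collapse = ", "))
    }
    gen <- trimws(raw[[1]])
    vals <- vapply(seq_along(env),
      function(j) parse_numeric_field(raw[[j + 1]], "value"),
      numeric(nrow(raw))
    )
    vals <- matrix(vals, nrow = length(gen), ncol = length(env))
    phenotype_table(vals, genotypes = gen, environments = env)
  } else {
    if (ncol(raw) < 3) stop("long layout needs columns genotype, environment, value")
    gen <- trimws(raw[[1]])
    env <- trimws(raw[[2]])
    val <- parse_numeric_field(raw[[3]], "value")
    gl <- unique(gen)
    el <- unique(env)
    gi <- match(gen, gl)
    ei <- match(env, el)
    sums <- matrix(0, length(gl), length(el))
    cnts <- matrix(0L, length(gl), length(el))
    keep <- !is.na(val)
    idx <- cbind(gi[keep], ei[keep])
    for (k in seq_len(nrow(idx))) {
      sums[idx[k, 1], idx[k, 2]] <- sums[idx[k, 1], idx[k, 2]] + val[keep][k]
      cnts[idx[k, 1], idx[k, 2]] <- cnts[idx[k, 1], idx[k, 2]] + 1L
    }
    vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
    phenotype_table(vals, genotypes = gl, environments = el)
  }
}

#' Write a phenotype table to delimited text
#'
#' Inverse of [read_phenotype_table()]: round-tripping either layout
#' reproduces the observed values exactly and preserves the missing mask.
#' The long layout emits observed cells only.
#'
#' @param x a [phenotype_table()].
#' @param path output file path.
#' @inheritParams read_phenotype_table
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(x, path, layout = c("wide", "long"), sep = ",") {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(genotype = rownames(x), check.names = FALSE)
    vals <- matrix("", nrow(x), ncol(x), dimnames = dimnames(x))
    vals[!is.na(x)] <- sprintf("%.17g", x[!is.na(x)])
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
    utils::write.table(df, path,
      sep = sep, row.names = FALSE, quote = FALSE, na = "")
  } else {
    obs <- which(!is.na(x), arr.ind = TRUE)
    obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
    df <- data.frame(
      genotype = rownames(x)[obs[, 1]],
      environment = colnames(x)[obs[, 2]],
      value = sprintf("%.17g", x[obs])
    )
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Marginal means over observed cells
#'
#' The overall mean and the per-genotype and per-environment means, each
#' computed over the observed cells only.  These are the margins entering the
#' response transformations of [gei_response()].
#'
#' @param x a [phenotype_table()].
#' @return A list with `overall` (scalar), `genotype` (named vector) and
#'   `environment` (named vector).
#' @export
margins <- function(x) {
  stopifnot(inherits(x, "phenotype_table"))
  list(
    overall = mean(x, na.rm = TRUE),
    genotype = rowMeans(x, na.rm = TRUE),
    environment = colMeans(x, na.rm = TRUE)
  )
}

#' Connectivity of the observed-cell pattern
#'
#' The bipartite graph with genotypes and environments as nodes and observed
#' cells as edges must be connected for the main effects of a global additive
#' model to be jointly estimable.  Fitters for global models refuse
#' disconnected tables.
#'
#' @param x a [phenotype_table()].
#' @return `TRUE` if the graph is connected, else `FALSE`.
#' @export
is_connected <- function(x) {
  stopifnot(inherits(x, "phenotype_table"))
  obs <- which(!is.na(x), arr.ind = TRUE)
  comp <- bipartite_components(obs[, 1], obs[, 2], nrow(x), ncol(x))
  comp$n_comp == 1L
}
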