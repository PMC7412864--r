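# Data model and I/O for a PBAE library: polymer identity codes, the
# polymer x descriptor matrix, validation and column standardization.

#' Format polymer identity codes
#'
#' A PBAE library member is identified by its diacrylate (a letter), its amine
#' (a small positive integer) and an optional end-capping agent. The canonical
#' string form is `"<acrylate><amine>"` for acrylate-terminated polymers
#' (e.g. `"A5"`) and `"<acrylate><amine>-<endcap>"` for end-capped ones
#' (e.g. `"A5-e2"`).
#'
#' @param acrylate Character vector of single-letter acrylate codes.
#' @param amine Integer vector of amine numbers (positive).
#' @param endcap Character vector of end-cap codes (`"e1"`, `"e2"` or
#'   `"none"`). `"none"` marks acrylate-terminated polymers and is omitted
#'   from the string form.
#' @return Character vector of polymer id strings.
#' @seealso [parse_polymer_id()]
#' @export
#' @examples
#' format_polymer_id("A", 5, "e2")
format_polymer_id <- function(acrylate, amine, endcap = "none") {
  stopifnot(is.character(acrylate), all(nzchar(acrylate)))
  amine <- as.integer(amine)
  if (any(is.na(amine)) || any(amine < 1L)) {
    stop("amine codes must be positive integers")
  }
  endcap <- as.character(endcap)
  bad <- !endcap %in% c("e1", "e2", "none")
  if (any(bad)) {
    stop("unknown endcap code(s): ", paste(unique(endcap[bad]), collapse = ", "))
  }
  k <- max(length(acrylate), length(amine), length(endcap))
  acrylate <- rep_len(acrylate, k)
  amine <- rep_len(amine, k)
  endcap <- rep_len(endcap, k)
  ifelse(endcap == "none",
         paste0(acrylate, amine),
         paste0(acrylate, amine, "-", endcap))
}

#' Parse polymer identity strings
#'
#' @param x Character vector of ids such as `"A5"` or `"B12-e1"`.
#' @return A data frame with columns `id`, `acrylate`, `amine`, `endcap`.
#' @export
parse_polymer_id <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)(-(e[0-9]+))?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed polymer id(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  data.frame(
    id = x,
    acrylate = vapply(m, `[`, "", 2L),
    amine = as.integer(vapply(m, `[`, "", 3L)),
    endcap = ifelse(vapply(m, `[`, "", 5L) == "", "none",
                    vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a polymer descriptor table
#'
#' The central container of the package: a dense numeric matrix of polymers
#' (rows) by physicochemical descriptors (columns), with a per-column source
#' tag recording whether a descriptor belongs to the amine monomer, the
#' acrylate monomer, the repeat unit, or was measured experimentally on the
#' polymer (molecular weights, zeta potential, hydrodynamic size, drug
#' loading, diffusion coefficient).
#'
#' @param values Numeric matrix, polymers in rows, descriptors in columns.
#'   Must have column names (descriptor names).
#' @param polymer_ids Character vector of unique polymer ids, one per row.
#'   Defaults to `rownames(values)`.
#' @param column_meta Optional character vector (one per column) with source
#'   tags in `c("amine", "acrylate", "repeat_unit", "experimental")`.
#' @return An object of class `descriptor_table` with elements `values`,
#'   `polymer_ids`, `descriptor_names`, `column_meta`.
#' @export
descriptor_table <- function(values, polymer_ids = rownames(values),
                             column_meta = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("descriptor values must be numeric")
  if (is.null(colnames(values))) stop("descriptor columns must be named")
  if (anyDuplicated(colnames(values))) {
    stop("duplicate descriptor names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (is.null(polymer_ids)) stop("polymer_ids are required")
  polymer_ids <- as.character(polymer_ids)
  if (length(polymer_ids) != nrow(values)) {
    stop("length(polymer_ids) != nrow(values)")
  }
  if (anyDuplicated(polymer_ids)) {
    stop("duplicate polymer id(s): ",
         paste(unique(polymer_ids[duplicated(polymer_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    coords <- paste0(polymer_ids[bad[, 1L]], "/", colnames(values)[bad[, 2L]])
    stop("non-finite descriptor value(s) at: ",
         paste(utils::head(coords, 10L), collapse = ", "))
  }
  if (!is.null(column_meta)) {
    column_meta <- as.character(column_meta)
    if (length(column_meta) != ncol(values)) {
      stop("column_meta must have one entry per descriptor column")
    }
    ok <- column_meta %in% c("amine", "acrylate", "repeat_unit", "experimental")
    if (!all(ok)) {
      stop("unknown column_meta tag(s): ",
           paste(unique(column_meta[!ok]), collapse = ", "))
    }
  }
  rownames(values) <- polymer_ids
  structure(
    list(values = values,
         polymer_ids = polymer_ids,
         descriptor_names = colnames(values),
         column_meta = column_meta),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", length(x$polymer_ids), " polymers x ",
      length(x$descriptor_names), " descriptors\n", sep = "")
  if (!is.null(x$column_meta)) {
    tab <- table(x$column_meta)
    cat("  sources:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Read a descriptor table from CSV
#'
#' Expects a header row, a first column `polymer_id` with unique ids in the
#' `"<acrylate><amine>[-<endcap>]"` form, and numeric descriptor columns.
#' An optional YAML/JSON schema maps descriptor names to source tags.
#'
#' @param path Path to a UTF-8 CSV file ("." decimal separator).
#' @param schema Optional path to a YAML/JSON file, or a named list/character
#'   vector, mapping descriptor name to source tag.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("need a polymer_id column plus descriptor columns")
  ids <- as.character(df[[1L]])
  parse_polymer_id(ids)  # validates the id format
  vals <- df[, -1L, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, TRUE)
  if (any(not_num)) {
    stop("non-numeric descriptor column(s): ",
         paste(names(vals)[not_num], collapse = ", "))
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    coords <- paste0("row ", bad[, 1L], " (", ids[bad[, 1L]], "), column '",
                     colnames(m)[bad[, 2L]], "'")
    stop("missing value(s) at: ", paste(utils::head(coords, 10L),
                                        collapse = "; "))
  }
  meta <- NULL
  if (!is.null(schema)) {
    map <- if (is.character(schema) && length(schema) == 1L &&
               file.exists(schema)) {
      unlist(read_descriptor_schema(schema))
    } else {
      unlist(schema)
    }
    meta <- unname(map[colnames(m)])
    if (anyNA(meta)) {
      stop("schema lacks source tags for: ",
           paste(colnames(m)[is.na(meta)], collapse = ", "))
    }
  }
  message(sprintf("read %d polymers x %d descriptors from %s",
                  nrow(m), ncol(m), path))
  descriptor_table(m, polymer_ids = ids, column_meta = meta)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]: emits `polymer_id` as first column.
#'
#' @param table A [descriptor_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(polymer_id = table$polymer_ids, table$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a descriptor schema file
#'
#' The schema maps descriptor names to their source tag (`amine`, `acrylate`,
#' `repeat_unit`, `experimental`) and optionally a unit string. The canonical
#' descriptor set used for PBAE libraries ships with the package:
#' `system.file("extdata", "descriptor_schema.yaml", package = "pbaescreen")`.
#'
#' @param path YAML or JSON file. Each entry is either a bare tag string or a
#'   list with elements `source` and `unit`.
#' @return Named list mapping descriptor name to source tag (the unit, when
#'   present, is kept as an attribute `"units"`).
#' @export
read_descriptor_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  tags <- lapply(raw, function(e) if (is.list(e)) e$source else e)
  units <- vapply(raw, function(e) {
    if (is.list(e) && !is.null(e$unit)) as.character(e$unit) else NA_character_
  }, "")
  out <- stats::setNames(as.list(unlist(tags)), names(raw))
  attr(out, "units") <- stats::setNames(units, names(raw))
  out
}

#' Standardize descriptor columns
#'
#' Descriptors span incompatible physical units (Da, mV, nm, unitless), so
#' distances and PLS fits are computed on z-scored columns: each column is
#' centred on its mean and divided by its sample standard deviation
#' (denominator n - 1). Constant columns carry no information and would give
#' 0/0; they are excluded and flagged.
#'
#' @param table A [descriptor_table()], or a bare numeric matrix.
#' @return An object of class `standardized_table` with elements `base` (the
#'   input table restricted to retained columns), `z_values` (z-scored
#'   matrix), `column_means`, `column_sds`, and `dropped_constant` (names of
#'   excluded constant columns).
#' @export
standardize_descriptors <- function(table) {
  m <- if (inherits(table, "descriptor_table")) table$values else as.matrix(table)
  if (nrow(m) < 2L) stop("standardization needs at least 2 polymers")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  constant <- sdv == 0
  if (any(constant)) {
    warning("excluding constant descriptor column(s): ",
            paste(colnames(m)[constant], collapse = ", "))
  }
  keep <- !constant
  z <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep], "-"),
             2L, sdv[keep], "/")
  base <- if (inherits(table, "descriptor_table")) {
    descriptor_table(table$values[, keep, drop = FALSE],
                     polymer_ids = table$polymer_ids,
                     column_meta = table$column_meta[keep])
  } else {
    descriptor_table(m[, keep, drop = FALSE],
                     polymer_ids = rownames(m) %||% as.character(seq_len(nrow(m))))
  }
  structure(
    list(base = base,
         z_values = z,
         column_means = mu[keep],
         column_sds = sdv[keep],
         dropped_constant = colnames(m)[constant]),
    class = "standardized_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a descriptor table
#'
#' Report-only checks: missing values, constant columns, and pairs of
#' descriptors whose absolute Pearson correlation exceeds a threshold. PBAE
#' descriptor sets are strongly multicollinear, which is why the modelling
#' layer uses PLS rather than ordinary regression; this report surfaces that
#' structure up front.
#'
#' @param table A [descriptor_table()].
#' @param cor_threshold Absolute correlation above which a descriptor pair is
#'   reported (default 0.95).
#' @return A list of class `library_validation` with elements `n_polymers`,
#'   `n_descriptors`, `missing` (coordinate data frame), `constant_columns`,
#'   `high_correlations` (data frame: descriptor_a, descriptor_b, r) and
#'   `clean` (logical).
#' @export
validate_library <- function(table, cor_threshold = 0.95) {
  stopifnot(inherits(table, "descriptor_table"))
  m <- table$values
  miss <- which(!is.finite(m), arr.ind = TRUE)
  missing <- data.frame(
    polymer_id = table$polymer_ids[miss[, 1L]],
    descriptor = colnames(m)[miss[, 2L]],
    stringsAsFactors = FALSE
  )
  sdv <- apply(m, 2L, stats::sd)
  const <- colnames(m)[sdv == 0]
  vary <- m[, sdv > 0, drop = FALSE]
  hi <- data.frame(descriptor_a = character(), descriptor_b = character(),
                   r = numeric(), stringsAsFactors = FALSE)
  if (ncol(vary) >= 2L) {
    cc <- stats::cor(vary)
    idx <- which(upper.tri(cc) & abs(cc) >= cor_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      hi <- data.frame(
        descriptor_a = colnames(vary)[idx[, 1L]],
        descriptor_b = colnames(vary)[idx[, 2L]],
        r = cc[idx],
        stringsAsFactors = FALSE
      )
      hi <- hi[order(-abs(hi$r)), , drop = FALSE]
      rownames(hi) <- NULL
    }
  }
  structure(
    list(n_polymers = nrow(m), n_descriptors = ncol(m),
         missing = missing, constant_columns = const,
         high_correlations = hi, cor_threshold = cor_threshold,
         clean = nrow(missing) == 0L && length(const) == 0L && nrow(hi) == 0L),
    class = "library_validation"
  )
}

#' @export
print.library_validation <- function(x, ...) {
  cat("<library_validation> ", x$n_polymers, " x ", x$n_descriptors, "\n",
      sep = "")
  cat("  missing cells:    ", nrow(x$missing), "\n")
  cat("  constant columns: ", length(x$constant_columns), "\n")
  cat("  |r| >= ", x$cor_threshold, " pairs: ", nrow(x$high_correlations),
      "\n", sep = "")
  invisible(x)
}
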