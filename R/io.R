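#' Read a delimited table as a mixed sample with blocks
#'
#' Reads a CSV or TSV file with a header row and a column specification
#' declaring, for each used column, its type (qualitative or quantitative)
#' and block membership (X, Y, Z, or ignore). Qualitative columns are
#' code-mapped deterministically: raw labels are sorted lexically and mapped
#' to codes `0, 1, 2, ...`, so the coding is stable across runs for
#' identical files. Quantitative columns are parsed as reals. Any missing or
#' unparseable cell is an error naming its row and column; rows with missing
#' data must be removed beforehand.
#'
#' @param path path to a delimited text file; `.tsv`/`.txt` are read as
#'   tab-separated, anything else as comma-separated.
#' @param column_spec a data.frame with columns `name`, `type`
#'   (`"qualitative"`/`"quantitative"`, shorthands `"l"`/`"t"`) and `block`
#'   (`"X"`, `"Y"`, `"Z"` or `"ignore"`), or the path to a CSV file with
#'   those columns.
#' @return A list with elements `sample` (a `mixed_sample` over the used
#'   columns), `x`, `y`, `z` (column names per block) and `codes` (the
#'   label-to-code maps of the qualitative columns).
#' @export
read_mixed_table <- function(path, column_spec) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(column_spec) && length(column_spec) == 1L)
    column_spec <- utils::read.csv(column_spec, stringsAsFactors = FALSE)
  spec <- as.data.frame(column_spec, stringsAsFactors = FALSE)
  req <- c("name", "type", "block")
  if (!all(req %in% names(spec)))
    stop("'column_spec' needs columns: ", paste(req, collapse = ", "))
  spec$block <- toupper(spec$block)
  spec <- spec[spec$block != "IGNORE", , drop = FALSE]
  if (!all(spec$block %in% c("X", "Y", "Z")))
    stop("block must be one of X, Y, Z, ignore")
  if (sum(spec$block == "X") < 1L || sum(spec$block == "Y") < 1L)
    stop("at least one column must be assigned to each of X and Y")
  if (anyDuplicated(spec$name))
    stop("each column may appear only once in 'column_spec'")

  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(spec$name, names(raw))
  if (length(missing_cols))
    stop("column(s) declared in spec but absent from file: ",
         paste(missing_cols, collapse = ", "))

  types <- normalize_types(spec$type, nrow(spec))
  codes <- list()
  mat <- matrix(NA_real_, nrow(raw), nrow(spec),
                dimnames = list(NULL, spec$name))
  for (j in seq_len(nrow(spec))) {
    nm <- spec$name[j]
    v <- raw[[nm]]
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("missing value in column '%s', row %d", nm, bad[1]))
    if (types[j] == "qualitative") {
      lev <- sort(unique(v))
      codes[[nm]] <- stats::setNames(seq_along(lev) - 1L, lev)
      mat[, j] <- codes[[nm]][v]
    } else {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value in quantitative column '%s', row %d",
                     nm, bad[1]))
      mat[, j] <- num
    }
  }
  list(sample = mixed_sample(mat, types),
       x = spec$name[spec$block == "X"],
       y = spec$name[spec$block == "Y"],
       z = spec$name[spec$block == "Z"],
       codes = codes)
}

#' Serialize an estimate or test result to JSON
#'
#' Writes a round-trippable JSON document (full numeric precision, scalars
#' unboxed) for a [cmih()] estimate, a [cmi_knn()] estimate or a
#' [cmi_test()] result, including the configuration echo and the package
#' version.
#'
#' @param result a `cmih_estimate`, `cmi_knn_estimate` or `cmi_test`
#'   object.
#' @param path output file path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_result <- function(result, path = NULL) {
  payload <- if (inherits(result, "cmih_estimate")) {
    list(type = "cmih_estimate", value = result$value,
         terms = as.list(result$terms), signs = result$signs,
         n = result$n, dims = as.list(result$dims),
         blocks = result$blocks)
  } else if (inherits(result, "cmi_knn_estimate")) {
    list(type = "cmi_knn_estimate", value = result$value,
         method = result$method, k = result$k, D_l = result$D_l,
         n = result$n)
  } else if (inherits(result, "cmi_test")) {
    list(type = "cmi_test", statistic = unname(result$statistic),
         p_value = result$p.value, B = result$B,
         permuted = result$permuted,
         config = list(estimator = result$estimator,
                       scheme = result$scheme, k_perm = result$k_perm,
                       rank_transform = result$rank_transform,
                       seed = result$seed, n = result$n))
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  payload$version <- as.character(utils::packageVersion("cmih"))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
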