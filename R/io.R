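CANONICAL_FEATURES <- c("athlete_id", "workload", "time_point", "jump",
                        "rel_peak_force", "rel_peak_power",
                        "t_con_s", "t_peak_force_s")

#' Column mapping for third-party feature tables
#'
#' Maps canonical field names onto the column labels of an external
#' feature export (for instance a deposited study table whose schema is not
#' under our control), with unit declarations from a closed vocabulary.
#'
#' @param ... named arguments `canonical = "source column"`; canonical names
#'   must come from `athlete_id, workload, time_point, jump,
#'   rel_peak_force, rel_peak_power, t_con_s, t_peak_force_s`.
#'   Unspecified fields default to their canonical name.
#' @param time_unit `"s"` or `"ms"` for the two time features.
#' @return Object of class `column_mapping`.
#' @export
column_mapping <- function(..., time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  user <- list(...)
  bad <- setdiff(names(user), CANONICAL_FEATURES)
  if (length(bad)) {
    stop("unknown canonical field(s): ", paste(bad, collapse = ", "),
         "; expected among: ", paste(CANONICAL_FEATURES, collapse = ", "))
  }
  if (anyDuplicated(unlist(user))) stop("each source column may be mapped only once")
  map <- stats::setNames(CANONICAL_FEATURES, CANONICAL_FEATURES)
  map[names(user)] <- unlist(user)
  structure(list(map = map, time_unit = time_unit), class = "column_mapping")
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a long-format feature table
#'
#' Reads a delimited feature file (TSV or CSV by extension), renames columns
#' to the canonical schema through a [column_mapping], and converts time
#' units to seconds.
#'
#' @param path file path.
#' @param mapping a [column_mapping]; the identity mapping by default.
#' @return Canonicalised feature data frame.
#' @export
read_features <- function(path, mapping = column_mapping()) {
  stopifnot(inherits(mapping, "column_mapping"))
  x <- read_delim_auto(path)
  missing <- mapping$map[!mapping$map %in% names(x)]
  if (length(missing)) {
    stop("unmapped/missing required column(s): ",
         paste(sprintf("%s (expected source column '%s')",
                       names(missing), missing), collapse = ", "),
         "; available columns: ", paste(names(x), collapse = ", "))
  }
  out <- x[unname(mapping$map)]
  names(out) <- names(mapping$map)
  if (mapping$time_unit == "ms") {
    out$t_con_s <- out$t_con_s / 1000
    out$t_peak_force_s <- out$t_peak_force_s / 1000
  }
  out$time_point <- as.character(out$time_point)
  message("read ", nrow(out), " feature rows from ", path)
  out
}

#' Write a feature table (tab-delimited, header row)
#' @param features feature data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write study traces, manifest and generating truth to a directory
#'
#' One two-column file (`time_s`, `force_N`) per trial, a `manifest.tsv`
#' (athlete_id, workload, time_point, jump, path) and a `truth.tsv` of
#' generating parameters.
#'
#' @param study a `cmj_study`.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_traces <- function(study, dir) {
  stopifnot(inherits(study, "cmj_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  man$path <- file.path(dir, paste0(man$trace, ".tsv"))
  for (i in seq_along(study$traces)) {
    tr <- study$traces[[i]]
    utils::write.table(data.frame(time_s = tr$time, force_N = tr$force),
                       man$path[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read one force-trace file
#' @param path two-column delimited file (`time_s`, `force_N`).
#' @param meta optional metadata list.
#' @return A [force_trace].
#' @export
read_trace <- function(path, meta = list()) {
  x <- read_delim_auto(path)
  if (!all(c("time_s", "force_N") %in% names(x))) {
    stop("trace file must have columns time_s and force_N")
  }
  force_trace(x$time_s, x$force_N, meta = meta)
}

#' Read a directory of traces via its manifest
#' @param dir directory written by [write_traces].
#' @return Named list of [force_trace] objects with metadata attached.
#' @export
read_study_traces <- function(dir) {
  man <- read_delim_auto(file.path(dir, "manifest.tsv"))
  traces <- lapply(seq_len(nrow(man)), function(i) {
    read_trace(man$path[i],
               meta = list(athlete_id = man$athlete_id[i],
                           workload = man$workload[i],
                           time_point = as.character(man$time_point[i]),
                           jump = man$jump[i]))
  })
  names(traces) <- man$trace
  traces
}

#' Write PCA/fPCA result tables to a directory
#' @param result a `cmj_pca` or `cmj_fpca`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Vector of written paths, invisibly.
#' @export
write_scores <- function(result, dir, prefix = class(result)[1]) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  vt <- data.frame(pc = seq_along(result$prop), proportion = result$prop,
                   cumulative = result$cumprop)
  p <- file.path(dir, paste0(prefix, "_variance.tsv"))
  utils::write.table(vt, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, paste0(prefix, "_scores.tsv"))
  sc <- as.data.frame(result$scores)
  ri <- result$row_info %||% result$sample_info
  if (!is.null(ri)) sc <- cbind(ri, sc)
  utils::write.table(sc, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$loadings)) {
    p <- file.path(dir, paste0(prefix, "_loadings.tsv"))
    utils::write.table(data.frame(variable = rownames(result$loadings),
                                  result$loadings, check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
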