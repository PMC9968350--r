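#' Read and write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description column (defaults to the
#'   set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write study peak tables
#'
#' CSV with columns `study_id`, `n_patients`, `n_controls`, `x`, `y`, `z`,
#' `t` and optionally `measure`; one row per peak, zero-peak studies appear
#' as a single row with `NA` coordinates. Coordinates must be MNI mm
#' (Talairach inputs are not converted and must be transformed upstream).
#'
#' @param path CSV file path.
#' @return `read_peak_table()` returns a list of [study_record]s.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "n_patients", "n_controls", "x", "y", "z", "t")
  if (!all(need %in% names(df)))
    stop("peak table ", path, " must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$study_id), function(s) {
    pk <- s[!is.na(s$x), c("x", "y", "z", "t"), drop = FALSE]
    study_record(s$study_id[1], s$n_patients[1], s$n_controls[1],
                 peaks = pk,
                 measure = if ("measure" %in% names(s)) s$measure[1] else "ALFF")
  })
}

#' @rdname read_peak_table
#' @param studies list of [study_record]s.
#' @export
write_peak_table <- function(studies, path) {
  rows <- lapply(studies, function(s) {
    pk <- s$peaks
    if (!nrow(pk)) pk <- data.frame(x = NA_real_, y = NA_real_, z = NA_real_,
                                    t = NA_real_)
    data.frame(study_id = s$study_id, n_patients = s$n_patients,
               n_controls = s$n_controls, pk, measure = s$measure)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write interaction edge lists
#'
#' Three-column TSV: `gene_a`, `gene_b`, `score`.
#'
#' @param path TSV file path.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(df)))
  df
}

#' @rdname read_edges
#' @param edges edge data frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
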