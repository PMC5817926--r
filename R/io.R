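# Plain-text interchange formats.
#
# Trace: TSV with '#'-prefixed metadata header lines, columns
#   time_s, force_pN, extension_nm, segment.
# Dataset: CSV with '#'-prefixed schema/metadata lines and the
#   refolding-record columns.
# Both carry a schema version line so readers can reject unknown layouts.

.FC_TRACE_SCHEMA <- "fc-trace/1"
.FC_DATASET_SCHEMA <- "fc-dataset/1"

#' Write a force-clamp trajectory to a TSV trace file
#'
#' @param trace an \code{fc_trajectory} from
#'   \code{\link{simulate_experiment}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "fc_trajectory")) stop("trace must be an fc_trajectory")
  md <- trace$metadata
  hdr <- c(paste0("# schema=", .FC_TRACE_SCHEMA),
           sprintf("# recording_id=%s", md$recording_id),
           sprintf("# condition=%s", md$condition),
           sprintf("# n_domains=%s", md$n_domains),
           sprintf("# seed=%s", md$seed),
           sprintf("# sampling_rate=%s", md$sampling_rate),
           sprintf("# step_size=%s", md$step_size))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(time_s = trace$time, force_pN = trace$force,
                   extension_nm = trace$extension, segment = trace$segment)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a force-clamp trajectory written by \code{\link{write_trace}}
#'
#' @param path trace TSV file.
#' @return an \code{fc_trajectory} (without ground-truth events).
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  if (!any(grepl(paste0("schema=", .FC_TRACE_SCHEMA), hdr)))
    stop("not a recognised trace file: ", path)
  kv <- sub("^#\\s*", "", hdr[-1])
  md <- strsplit(kv, "=", fixed = TRUE)
  meta <- setNames(lapply(md, function(p) {
    v <- p[2]
    if (grepl("^-?[0-9.eE+]+$", v)) as.numeric(v) else v
  }), vapply(md, `[`, "", 1))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(time = df$time_s, force = df$force_pN,
                 extension = df$extension_nm, segment = df$segment,
                 metadata = meta, events = NULL),
            class = "fc_trajectory")
}

#' Write a refolding dataset to CSV
#'
#' @param dataset data.frame of refolding records (one row per recording)
#'   as produced by \code{\link{simulate_experiment}}.
#' @param path output CSV path.
#' @param metadata optional named list written into the header.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema=", .FC_DATASET_SCHEMA), con)
  for (k in names(metadata))
    writeLines(sprintf("# %s=%s", k, metadata[[k]]), con)
  write.table(dataset, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a refolding dataset written by \code{\link{write_dataset}}
#'
#' @param path dataset CSV path.
#' @return the records data.frame; header metadata in
#'   \code{attr(, "metadata")}.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!any(grepl(paste0("schema=", .FC_DATASET_SCHEMA), hdr)))
    stop("not a recognised dataset file: ", path)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = ",", stringsAsFactors = FALSE)
  kv <- strsplit(sub("^#\\s*", "", hdr[-1]), "=", fixed = TRUE)
  attr(df, "metadata") <- setNames(lapply(kv, `[`, 2),
                                   vapply(kv, `[`, "", 1))
  df
}

#' Write analysis results as JSON
#'
#' @param results a named list (per condition: yield, sem, counts, fits).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Thin wrapper around \code{seqinr::read.fasta} returning upper-case
#' protein sequences as a named character vector.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_aa <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  setNames(toupper(unlist(seqs)), names(seqs))
}
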