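#' Read and write connectome matrix files
#'
#' Connectome matrices are stored as tab-delimited text: the first row and
#' first column carry the region labels, and cell (i, j) holds the integer
#' fiber count.  The format is lossless for counts and human-inspectable.
#' `read_connectome()` validates every matrix invariant (square, symmetric,
#' integer, non-negative, zero diagonal) and names the first offending cell
#' on failure.
#'
#' @param path File path.
#' @param parcellation Optional [parcellation()] the file must match; when
#'   `NULL` the labels in the file are used.
#' @param subject_id,session,setting Metadata to attach (from a manifest or
#'   caller); `setting` is required.
#' @return `read_connectome()`: a [connectome()]; `write_connectome()`:
#'   `path`, invisibly.
#' @export
read_connectome <- function(path, setting, subject_id = "unknown",
                            session = "1", parcellation = NULL) {
  if (!file.exists(path)) stop("connectome file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, colClasses = "character")
  labs <- rownames(df)
  if (!identical(labs, colnames(df))) {
    stop("format error in ", path, ": row labels do not match column labels",
         call. = FALSE)
  }
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("format error in %s: non-numeric entry at cell (%d, %d)",
                 path, bad[1L], bad[2L]), call. = FALSE)
  }
  if (!is.null(parcellation) && !identical(labs, parcellation$region_labels)) {
    stop("region labels in ", path, " do not match the supplied parcellation",
         call. = FALSE)
  }
  connectome(structure(m, dimnames = list(labs, labs)),
             subject_id = subject_id, session = session, setting = setting)
}

#' @rdname read_connectome
#' @param connectome A [connectome()] to write.
#' @export
write_connectome <- function(connectome, path) {
  stopifnot(inherits(connectome, "connectome"))
  m <- connectome$matrix
  labs <- connectome$parcellation$region_labels
  cells <- if (isTRUE(connectome$continuous)) format_full(m) else format(m, scientific = FALSE, trim = TRUE)
  body <- matrix(cells, nrow(m), ncol(m))
  lines <- c(
    paste(c("region", labs), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(r) paste(c(labs[r], body[r, ]), collapse = "\t"),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A cohort manifest is a CSV table with header
#' `subject_id,session,res_mm,bval,path`; each row points at one connectome
#' matrix file (path relative to the manifest's directory unless absolute).
#' All referenced matrices are loaded, validated, and assembled into a
#' [cohort()]; duplicate keys, missing files, and mixed parcellations are
#' errors.
#'
#' @param path Manifest CSV path.
#' @return A [cohort()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject_id", "res_mm", "bval", "path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("manifest ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$session)) df$session <- "1"
  df$session[!nzchar(df$session)] <- "1"
  base <- dirname(path)
  conns <- lapply(seq_len(nrow(df)), function(k) {
    f <- df$path[k]
    if (!file.exists(f)) f <- file.path(base, df$path[k])
    read_connectome(f,
                    setting = acq_setting(as.numeric(df$res_mm[k]), as.numeric(df$bval[k])),
                    subject_id = df$subject_id[k], session = df$session[k])
  })
  cohort(conns)
}

#' Write a cohort as matrix files plus a manifest
#'
#' Writes one TSV matrix per connectome into `dir` and a `manifest.csv`
#' indexing them (paths relative to the manifest), the same layout
#' [read_manifest()] consumes.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name within `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest = "manifest.csv") {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$connectomes, function(cn) {
    fname <- sprintf("sc_%s_ses-%s_res-%g_bval-%g.tsv",
                     cn$subject_id, cn$session, cn$setting$res, cn$setting$bval)
    write_connectome(cn, file.path(dir, fname))
    data.frame(subject_id = cn$subject_id, session = cn$session,
               res_mm = format_full(cn$setting$res),
               bval = format_full(cn$setting$bval),
               path = fname, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mpath <- file.path(dir, manifest)
  utils::write.csv(man, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
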