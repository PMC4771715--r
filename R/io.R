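#' Read ChIP-seq peak calls from a BED file
#'
#' Peaks are returned as a `GRanges` in the usual Bioconductor 1-based
#' closed convention; the 0-based half-open BED coordinates on disk are
#' converted on the way in (and back on the way out by [write_peaks()]),
#' so a write/read round trip is exact.  BED3 through BED6 are accepted;
#' gzip-compressed files are transparent.
#'
#' @param path path to a BED3+ file (optionally `.gz`).
#' @return `GRanges`, one range per peak, input order preserved; a `name`
#'   metadata column when the file has one (peaks without a name get a
#'   stable `chrom:start-end` identifier).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  .check_widths(gr, path)
  if (length(gr) == 0L) {
    gr$name <- character()
    return(gr)
  }
  if (is.null(gr$name) || anyNA(gr$name)) {
    nm <- peak_id(gr)
    if (!is.null(gr$name)) nm[!is.na(gr$name)] <- gr$name[!is.na(gr$name)]
    gr$name <- nm
  }
  gr
}

#' Write peaks to BED
#'
#' @param peaks `GRanges` of peaks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "bed")
  invisible(path)
}

# BED/bedGraph lines with start >= end are silently dropped or misread by
# generic importers; reject them so coordinate bugs surface at the boundary.
.check_widths <- function(gr, path) {
  bad <- which(width(gr) < 1L)
  if (length(bad) > 0L)
    stop("record ", bad[1L], " of '", path, "' has start >= end", call. = FALSE)
  invisible(gr)
}

#' Stable peak identifiers
#'
#' `chrom:start-end` labels (1-based closed, as printed by genome browsers).
#'
#' @param gr a `GRanges`.
#' @return character vector of identifiers.
#' @export
peak_id <- function(gr) {
  if (length(gr) == 0L) return(character())
  paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))
}

#' Read a transcript annotation (GFF3 or BED12)
#'
#' Returns one range per transcript with `gene_id` and `transcript_id`
#' metadata and a mandatory strand, the inputs required by
#' [assign_peaks()].  From GFF3, features of type `transcript` or `mRNA`
#' are used (other feature types are skipped with a message giving the
#' count); `gene_id` falls back to `Parent`, then to the transcript's own
#' ID for single-level annotations.  From BED12/BED6 the `name` column
#' serves as both identifiers (BED carries no gene/transcript distinction).
#'
#' @param path path to the annotation file (optionally `.gz`).
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @return `GRanges` with `gene_id` and `transcript_id` metadata columns.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.bed([0-9]*)$", base, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("transcript", "mRNA")
    n_skip <- sum(!keep)
    if (n_skip > 0L)
      message("read_annotation: skipped ", n_skip,
              " non-transcript feature(s)")
    gr <- gr[keep]
    tid <- as.character(gr$ID)
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else rep(NA_character_, length(gr))
    if (anyNA(gid) && !is.null(gr$Parent)) {
      par <- vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
      gid[is.na(gid)] <- par[is.na(gid)]
    }
    gid[is.na(gid)] <- tid[is.na(gid)]
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    .check_widths(gr, path)
    tid <- gid <- if (!is.null(gr$name)) as.character(gr$name) else peak_id(gr)
  }
  if (any(as.character(strand(gr)) == "*"))
    stop("annotation '", path, "' has transcripts without a strand", call. = FALSE)
  if (anyDuplicated(tid))
    stop("duplicated transcript_id in '", path, "': ",
         tid[anyDuplicated(tid)], call. = FALSE)
  out <- granges(gr)
  mcols(out) <- S4Vectors::DataFrame(gene_id = gid, transcript_id = tid)
  out
}

#' Write a transcript annotation to GFF3
#'
#' Comment headers that vary between runs (date, tool version) are
#' stripped so identical annotations produce byte-identical files.
#'
#' @param transcripts `GRanges` with `gene_id`/`transcript_id` metadata.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  gr <- transcripts
  gr$ID <- gr$transcript_id
  gr$type <- "transcript"
  gr$transcript_id <- NULL
  rtracklayer::export(gr, path, format = "gff3")
  lines <- readLines(path)
  keep <- !grepl("^##(source-version|date)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

#' Read a per-base tag coverage track (bedGraph)
#'
#' The track is a step function: non-overlapping scored segments, zero
#' outside them.  Returned sorted; overlapping segments are rejected.
#'
#' @param path path to a bedGraph file (optionally `.gz`).
#' @return `GRanges` with a numeric `score` column, sorted.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  .check_widths(gr, path)
  if (length(gr) == 0L) {
    gr$score <- numeric()
    return(gr)
  }
  gr <- GenomicRanges::sort(gr)
  hit <- findOverlaps(gr, drop.self = TRUE)
  if (length(hit) > 0L)
    stop("coverage '", path, "' has overlapping segments", call. = FALSE)
  gr
}

#' Write a coverage track to bedGraph
#'
#' @param cov `GRanges` with a `score` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  rtracklayer::export(cov, path, format = "bedGraph")
  invisible(path)
}

#' Read an RPKM expression matrix with its sample sheet
#'
#' The matrix is a TSV whose first column holds gene (or transcript)
#' identifiers and remaining columns one sample each.  The sample sheet is
#' a YAML sidecar mapping each sample to a condition (`control`, `kdA`,
#' `kdB`) and replicate index:
#'
#' ```yaml
#' samples:
#'   - {sample: ctrl_1, condition: control, replicate: 1}
#'   - {sample: kdA_1,  condition: kdA,     replicate: 1}
#' ```
#'
#' @param path TSV path.
#' @param samples_path YAML sample sheet path; `NULL` to return only the
#'   matrix.
#' @return list with `matrix` (numeric, rownames = gene ids) and `samples`
#'   (data.frame: sample, condition, replicate), columns ordered as in the
#'   sheet.
#' @export
read_expression <- function(path, samples_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs id column + samples")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1L]])
  if (any(mat < 0, na.rm = TRUE)) stop("negative RPKM values in ", path)
  samples <- NULL
  if (!is.null(samples_path)) {
    sheet <- yaml::read_yaml(samples_path)
    if (is.null(sheet$samples)) stop("sample sheet lacks a 'samples' key")
    samples <- do.call(rbind, lapply(sheet$samples, function(s) {
      data.frame(sample = as.character(s$sample),
                 condition = as.character(s$condition),
                 replicate = as.integer(s$replicate),
                 stringsAsFactors = FALSE)
    }))
    missing <- setdiff(samples$sample, colnames(mat))
    if (length(missing) > 0L)
      stop("samples absent from matrix: ", paste(missing, collapse = ", "))
    mat <- mat[, samples$sample, drop = FALSE]
  }
  list(matrix = mat, samples = samples)
}

#' Collapse a transcript-level expression matrix to gene level
#'
#' RPKM rows sharing a gene are summed, so downstream dependency calls are
#' made per gene.
#'
#' @param mat numeric matrix, rownames = transcript ids.
#' @param gene_map named character vector: `gene_map[transcript_id]` is the
#'   owning gene id.
#' @return numeric matrix with one row per gene.
#' @export
collapse_to_genes <- function(mat, gene_map) {
  if (is.null(rownames(mat))) stop("matrix must have rownames")
  genes <- gene_map[rownames(mat)]
  if (anyNA(genes))
    stop("transcripts missing from gene_map: ",
         paste(utils::head(rownames(mat)[is.na(genes)]), collapse = ", "))
  out <- rowsum(mat, group = as.character(genes), reorder = TRUE)
  out
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return named list of character vectors (members, de-duplicated).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}
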