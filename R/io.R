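## Readers/writers for the plain-text formats the pipeline touches.
## TSV is the only tabular dialect; ids match case-sensitively.

#' Read a counts matrix from TSV
#'
#' Expects a header row of sample ids; first column transcript ids. Counts
#' must be non-negative integers. When a sample sheet is supplied, every
#' column must be present in it (matrix columns are reordered to the sheet).
#'
#' @param path TSV file.
#' @param samples optional sample sheet (`data.frame` from
#'   [read_sample_sheet()]).
#' @return an [expr_matrix()] at stage `"counts"`.
#' @export
read_counts <- function(path, samples = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts file needs id column + >=1 sample: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated transcript ids in ", path, ": ",
         paste(head(dup, 5), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  }
  if (!is.null(samples)) {
    missing <- setdiff(colnames(vals), samples$sample_id)
    if (length(missing)) {
      stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
    }
    keep <- intersect(samples$sample_id, colnames(vals))
    vals <- vals[, keep, drop = FALSE]
    if (!is.null(samples$mapped_reads)) {
      mm <- samples$mapped_reads[match(colnames(vals), samples$sample_id)] / 1e6
      return(expr_matrix(vals, stage = "counts", mapped_reads_millions = mm))
    }
  }
  expr_matrix(vals, stage = "counts")
}

#' Write an expression matrix to TSV
#' @param m an [expr_matrix()].
#' @param path output file.
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(transcript_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (sample_id, animal, tissue, library)
#' @param path TSV file with those four columns.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "animal", "tissue", "library")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  validate_sample_sheet(df)
  # optional per-sample mapped-read totals (used by rpkm when present)
  keep <- c(need, intersect("mapped_reads", names(df)))
  df[keep]
}

validate_sample_sheet <- function(df) {
  tab <- table(df$tissue)
  if (any(tab < 2)) {
    warning("tissues with <2 samples cannot enter pairwise comparisons: ",
            paste(names(tab)[tab < 2], collapse = ", "))
  }
  invisible(df)
}

#' Read a transcript annotation table
#'
#' Columns `transcript_id`, `biotype`, `length_bp`; optional logical
#' `is_tf` (default FALSE). Biotypes come from the closed vocabulary
#' mRNA/miRNA/snRNA/snoRNA/misc.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "biotype", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id)) stop("duplicate transcript ids in ", path)
  bad <- setdiff(unique(df$biotype), BIOTYPES)
  if (length(bad)) stop("unknown biotype(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (any(df$length_bp <= 0)) stop("non-positive transcript length in ", path)
  if (is.null(df$is_tf)) df$is_tf <- FALSE
  df$is_tf <- as.logical(df$is_tf)
  df[c(need, "is_tf")]
}

#' Write an annotation table
#' @param annotation data.frame as returned by [read_annotation()].
#' @param path output TSV.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are uppercased and transcribed T->U; ids are the first
#' whitespace token of each header. Characters outside ACGUN and duplicate
#' ids are errors.
#'
#' @param path FASTA file.
#' @return named character vector id -> sequence.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("FASTA must start with a header: ", path)
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  if (length(seqs) < length(ids)) {
    # records whose body is absent entirely
    have <- as.integer(names(seqs))
    seqs <- seqs[match(seq_along(ids), have)]
  }
  seqs <- toupper(seqs)
  seqs <- chartr("T", "U", seqs)
  empty <- !nzchar(seqs) | is.na(seqs)
  if (any(empty)) stop("empty sequence for id(s): ", paste(ids[empty], collapse = ", "),
                       " in ", path)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("non-ACGUN characters in sequence(s): ", paste(ids[bad], collapse = ", "),
         " in ", path)
  }
  setNames(as.character(seqs), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector id -> sequence.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then member ids. Member lists are
#' deduplicated preserving order; sets with no members are dropped with a
#' warning.
#'
#' @param path GMT file.
#' @return named list of character vectors; `attr(, "description")` holds
#'   the per-set description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1))
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(members) < 1
  if (any(empty)) {
    warning("dropping gene sets with no members: ",
            paste(names[empty], collapse = ", "))
    names <- names[!empty]; desc <- desc[!empty]; members <- members[!empty]
  }
  if (anyDuplicated(names)) stop("duplicate gene-set names in ", path)
  sets <- setNames(members, names)
  attr(sets, "description") <- setNames(desc, names)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a co-expression network to GraphML or SIF
#'
#' GraphML carries node attributes (biotype, de_comparisons, is_tf,
#' rif_significant, hub, hub_centrality) and the signed edge correlation
#' `r`. The SIF dialect writes an edge list plus two attribute TSVs
#' (`<path>.nodes.tsv`, `<path>.edges.tsv`).
#'
#' @param network a `pcit_network` (see [build_network()]).
#' @param path output file.
#' @param dialect `"graphml"` or `"sif"`.
#' @export
write_network <- function(network, path, dialect = c("graphml", "sif")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "pcit_network"))
  g <- network$graph
  if (dialect == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(g, what = "edges")
    if (nrow(ed)) {
      sif <- data.frame(a = ed$from, interaction = "coexp", b = ed$to)
    } else {
      sif <- data.frame(a = character(0), interaction = character(0), b = character(0))
    }
    write.table(sif, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    nd <- igraph::as_data_frame(g, what = "vertices")
    write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(ed, paste0(path, ".edges.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML file.
#' @return a `pcit_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = g), class = "pcit_network")
}
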