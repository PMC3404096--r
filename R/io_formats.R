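# Readers and writers for the external formats the pipeline touches:
# 12-column tabular similarity hits, profile-hit TSV, annotation TSV, FASTA,
# Newick, Java TreeView CDT/GTR/ATR, and a flat key=value config file.
# Readers never drop a row silently: every rejected row raises or is messaged
# with its line number and a reason.

HIT_COLUMNS <- c("query_id", "subject_id", "pident", "aln_len", "mismatches",
                 "gaps", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Read a 12-column tabular similarity hit file
#'
#' Parses the de facto 12-column tab-separated dialect of protein search output
#' (query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score). Coordinates are
#' 1-based inclusive; alignment spans are `end - start + 1`.
#'
#' When an annotation table is supplied, query and subject coverage fractions
#' are computed as the aligned span divided by the sequence length from the
#' annotation table (`length_aa`). Hits referencing gene ids absent from the
#' annotation table are kept with `NA` coverage and a warning.
#'
#' @param path path to the tab-separated hit file (no header).
#' @param annotations optional gene annotation table (see [read_annotations()])
#'   used to supply sequence lengths for coverage computation.
#' @return a `data.frame` with columns `query_id`, `subject_id`, `bitscore`,
#'   `evalue`, `q_cov`, `s_cov` (one row per hit).
#' @seealso [write_similarity_hits()], [read_profile_hits()]
#' @export
read_similarity_hits <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  lineno <- which(nzchar(raw))
  lines <- raw[lineno]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      q_cov = numeric(), s_cov = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop(sprintf("malformed hit row at line %d: expected 12 columns, found %d",
                 lineno[bad], nf[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  colnames(m) <- HIT_COLUMNS
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10, dimnames = list(NULL, HIT_COLUMNS[3:12]))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop(sprintf("malformed hit row at line %d: unparseable numeric field",
                 lineno[bad]), call. = FALSE)
  }
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     bitscore = num[, "bitscore"], evalue = num[, "evalue"],
                     q_cov = NA_real_, s_cov = NA_real_,
                     stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) {
    bad <- which(hits$evalue < 0)[1]
    stop(sprintf("malformed hit row at line %d: negative E-value",
                 lineno[bad]), call. = FALSE)
  }
  q_span <- num[, "qend"] - num[, "qstart"] + 1
  s_span <- num[, "send"] - num[, "sstart"] + 1
  if (!is.null(annotations)) {
    len <- setNames(annotations$length_aa, annotations$gene_id)
    unknown <- unique(c(hits$query_id, hits$subject_id))
    unknown <- unknown[!unknown %in% names(len)]
    if (length(unknown) > 0) {
      warning(sprintf("%d gene id(s) in hit table missing from annotations (e.g. %s); rows kept with NA coverage",
                      length(unknown), unknown[1]), call. = FALSE)
    }
    hits$q_cov <- q_span / unname(len[hits$query_id])
    hits$s_cov <- s_span / unname(len[hits$subject_id])
  }
  hits
}

#' Write similarity hits in the 12-column tabular dialect
#'
#' Inverse of [read_similarity_hits()]. Alignment coordinates are synthesised
#' from the coverage fractions and the gene lengths in `annotations`
#' (`qstart = 1`, `qend = round(q_cov * length)` and likewise for the subject);
#' percent identity, mismatches and gap counts are placeholders since the
#' pipeline never consumes them.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `bitscore`, `evalue`,
#'   `q_cov`, `s_cov`.
#' @param annotations gene annotation table supplying `length_aa` per gene.
#' @param path output path.
#' @export
write_similarity_hits <- function(hits, annotations, path) {
  len <- setNames(annotations$length_aa, annotations$gene_id)
  qlen <- unname(len[hits$query_id])
  slen <- unname(len[hits$subject_id])
  if (anyNA(qlen) || anyNA(slen))
    stop("hit table references gene ids missing from annotations", call. = FALSE)
  qend <- pmax(1L, round(hits$q_cov * qlen))
  send <- pmax(1L, round(hits$s_cov * slen))
  out <- data.frame(hits$query_id, hits$subject_id, 95.0, qend, 0L, 0L,
                    1L, qend, 1L, send,
                    sprintf("%.3e", hits$evalue),
                    sprintf("%.3f", hits$bitscore))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read or write a profile-hit table
#'
#' Profile hits are the minimal distillation of profile-versus-proteome search
#' output used downstream: one row per (gene, profile) pair with the hit
#' E-value and the fraction of the gene and of the profile covered by the hit.
#'
#' @param path path to a tab-separated file with header columns `gene_id`,
#'   `profile_id`, `evalue`, `cov_gene`, `cov_profile`.
#' @return `data.frame` with those five columns.
#' @export
read_profile_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "profile_id", "evalue", "cov_gene", "cov_profile")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("profile hit table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[need]
  bad <- which(is.na(df$evalue) | df$evalue < 0 |
                 is.na(df$cov_gene) | df$cov_gene < 0 | df$cov_gene > 1 |
                 is.na(df$cov_profile) | df$cov_profile < 0 | df$cov_profile > 1)
  if (length(bad) > 0)
    stop(sprintf("malformed profile hit at line %d: E-value must be >= 0 and coverages in [0, 1]",
                 bad[1] + 1L), call. = FALSE)
  df
}

#' @rdname read_profile_hits
#' @param hits profile-hit `data.frame` to write.
#' @export
write_profile_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a gene annotation table
#'
#' The annotation TSV is the contract with upstream annotation engines: one row
#' per protein-coding gene with its genome, genus, free-text product
#' annotation, COG category letters (concatenated, possibly empty) and protein
#' length in amino acids. A file lacking the `cog` column parses permissively
#' to records with an empty category set.
#'
#' @param path path to a tab-separated file with header; required columns
#'   `gene_id`, `genome_id`, `genus_id`, `product`, `length_aa`; optional
#'   column `cog`.
#' @return `data.frame` with columns `gene_id`, `genome_id`, `genus_id`,
#'   `product`, `cog`, `length_aa`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  need <- c("gene_id", "genome_id", "genus_id", "product", "length_aa")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("annotation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"cog" %in% names(df)) df$cog <- ""
  df <- df[c("gene_id", "genome_id", "genus_id", "product", "cog", "length_aa")]
  df$length_aa <- suppressWarnings(as.integer(df$length_aa))
  bad <- which(is.na(df$length_aa) | df$length_aa < 1)
  if (length(bad) > 0)
    stop(sprintf("malformed annotation at line %d: length_aa must be a positive integer",
                 bad[1] + 1L), call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation table: ",
         df$gene_id[anyDuplicated(df$gene_id)], call. = FALSE)
  letters_used <- unique(unlist(strsplit(df$cog, "", fixed = TRUE)))
  bad_letters <- setdiff(letters_used, COG_ALPHABET)
  if (length(bad_letters) > 0)
    stop("unknown COG category letter(s): ",
         paste(bad_letters, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_annotations
#' @param genes annotation `data.frame` to write.
#' @export
write_annotations <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file to a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; tolerates wrapped lines
#' and CRLF line endings. Sequence names are truncated at the first
#' whitespace.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- gsub("\r", "", seqs, fixed = TRUE)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Wrapper over [ape::read.tree()] preserving branch lengths and internal node
#' labels; raises an error (with the offending text) rather than returning
#' `NULL` on a syntax error.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr))
    stop("Newick syntax error in ", path, ": ",
         substr(paste(readLines(path), collapse = ""), 1, 60), call. = FALSE)
  tr
}

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#'
#' @param path path to the config file.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop(sprintf("malformed config line %d: expected 'key = value'", bad[1]),
         call. = FALSE)
  vals <- lapply(parts, function(p) trimws(p[3]))
  names(vals) <- vapply(parts, function(p) trimws(p[2]), character(1))
  vals
}

# ---------------------------------------------------------------------------
# Java TreeView CDT / GTR / ATR
# ---------------------------------------------------------------------------

dendro_node_ids <- function(dend, prefix) {
  # leaf i -> "<prefix><i-1>X", internal merge step k -> "NODE<k>X"
  list(leaf = sprintf("%s%dX", prefix, seq_along(dend$labels) - 1L),
       node = sprintf("NODE%dX", seq_len(nrow(dend$merge))))
}

write_tree_file <- function(dend, prefix, path) {
  ids <- dendro_node_ids(dend, prefix)
  ref <- function(v) {
    out <- character(length(v))
    neg <- v < 0
    out[neg] <- ids$leaf[-v[neg]]
    out[!neg] <- ids$node[v[!neg]]
    out
  }
  out <- data.frame(ids$node, ref(dend$merge[, 1]), ref(dend$merge[, 2]),
                    format(dend$height, trim = TRUE, scientific = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Export a clustered presence/absence matrix as Java TreeView CDT/GTR/ATR
#'
#' Writes `<path_stem>.cdt` (clustered data table with `GID`, `NAME` and
#' `GWEIGHT` columns, an `AID` row and an `EWEIGHT` row, all weights 1) plus
#' `<path_stem>.gtr` / `<path_stem>.atr` node files when a row / column
#' dendrogram is supplied. Rows and columns appear in dendrogram leaf order;
#' node heights are written in raw Manhattan-distance units. Binary matrices
#' are written as integers (Java TreeView compatibility).
#'
#' @param mat numeric matrix with row and column names (tribes x genomes).
#' @param row_dend,col_dend dendrograms from [cluster_matrix()] whose leaf
#'   label sets must equal the matrix row / column name sets, or `NULL` to
#'   keep natural order (no tree file written for that axis).
#' @param path_stem output path without extension.
#' @return invisibly, the paths written.
#' @seealso [read_cdt()] for the lossless round trip.
#' @export
write_cdt <- function(mat, row_dend = NULL, col_dend = NULL, path_stem) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must have row and column names", call. = FALSE)
  row_order <- seq_len(nrow(mat))
  col_order <- seq_len(ncol(mat))
  if (!is.null(row_dend)) {
    if (!setequal(row_dend$labels, rownames(mat)))
      stop("row dendrogram leaves do not match matrix rows", call. = FALSE)
    row_order <- match(row_dend$labels[row_dend$order], rownames(mat))
  }
  if (!is.null(col_dend)) {
    if (!setequal(col_dend$labels, colnames(mat)))
      stop("column dendrogram leaves do not match matrix columns", call. = FALSE)
    col_order <- match(col_dend$labels[col_dend$order], colnames(mat))
  }
  gid <- sprintf("GENE%dX", row_order - 1L)
  aid <- sprintf("ARRY%dX", col_order - 1L)
  vals <- mat[row_order, col_order, drop = FALSE]
  fmt <- if (all(vals %in% c(0, 1))) {
    format(as.integer(vals), trim = TRUE)
  } else {
    format(vals, trim = TRUE, scientific = FALSE)
  }
  body <- matrix(fmt, nrow = nrow(vals))
  paths <- paste0(path_stem, ".cdt")
  con <- file(paths[1], "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "NAME", "GWEIGHT", colnames(vals)),
                   collapse = "\t"), con)
  writeLines(paste(c("AID", "", "", aid), collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", rep("1", ncol(vals))),
                   collapse = "\t"), con)
  writeLines(paste(gid, rownames(vals), "1",
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  if (!is.null(row_dend)) {
    p <- paste0(path_stem, ".gtr")
    write_tree_file(reindex_dendro(row_dend, rownames(mat)), "GENE", p)
    paths <- c(paths, p)
  }
  if (!is.null(col_dend)) {
    p <- paste0(path_stem, ".atr")
    write_tree_file(reindex_dendro(col_dend, colnames(mat)), "ARRY", p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Re-express a dendrogram's leaf indices against an external label ordering so
# GENE/ARRY ids refer to the matrix's own row/column positions.
reindex_dendro <- function(dend, ext_labels) {
  map <- match(dend$labels, ext_labels)
  merge <- dend$merge
  neg <- merge < 0
  merge[neg] <- -map[-merge[neg]]
  list(merge = merge, height = dend$height, order = dend$order,
       labels = ext_labels)
}

#' Read back a CDT file (with optional GTR/ATR)
#'
#' Lossless counterpart of [write_cdt()] for matrix values and leaf orderings:
#' the returned matrix rows/columns are in file (i.e. clustered) order.
#'
#' @param path_stem path without extension, as given to [write_cdt()].
#' @return list with `matrix` (numeric, named), `gtr` and `atr`
#'   (`data.frame`s of node records or `NULL`).
#' @export
read_cdt <- function(path_stem) {
  path <- paste0(path_stem, ".cdt")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (!identical(header[1:3], c("GID", "NAME", "GWEIGHT")))
    stop("not a CDT file (expected GID/NAME/GWEIGHT header): ", path,
         call. = FALSE)
  genomes <- header[-(1:3)]
  body <- fields[!vapply(fields, function(f) f[1] %in% c("GID", "AID", "EWEIGHT"),
                         logical(1))]
  vals <- t(vapply(body, function(f) as.numeric(f[-(1:3)]),
                   numeric(length(genomes))))
  if (length(genomes) == 1) vals <- matrix(vals, ncol = 1)
  rownames(vals) <- vapply(body, `[`, character(1), 2)
  colnames(vals) <- genomes
  read_tree_file <- function(p) {
    if (!file.exists(p)) return(NULL)
    df <- read.delim(p, header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("node", "left", "right", "height"))
    df
  }
  list(matrix = vals,
       gtr = read_tree_file(paste0(path_stem, ".gtr")),
       atr = read_tree_file(paste0(path_stem, ".atr")))
}
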