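#' Read a FASTA file into a named character vector
#'
#' Sequences are returned as a named character vector (one element per
#' record, names are the full header lines up to the first whitespace).
#' Case is preserved: lowercase letters mark soft-masked positions and
#' survive a round-trip.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1L], " in ", path)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) stop("empty sequence for id ", ids[!nzchar(seqs)][1L])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' Quality strings are parsed but discarded: quality trimming happens
#' upstream of this pipeline. Mate files must list reads in the same
#' order.
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return data.frame with columns `id`, `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readBStringSet(r1, format = "fastq")
  s2 <- Biostrings::readBStringSet(r2, format = "fastq")
  if (length(s1) != length(s2))
    stop("mate files differ in read count: ", length(s1), " vs ", length(s2))
  ids <- sub("\\s.*$", "", names(s1))
  ids <- sub("/[12]$", "", ids)
  read_pairs(ids, as.character(s1), as.character(s2))
}

#' Construct a read-pair table
#'
#' @param id Character vector of pair ids.
#' @param mate1,mate2 Nucleotide strings, one per pair.
#' @return data.frame with columns `id`, `mate1`, `mate2`.
#' @export
read_pairs <- function(id, mate1, mate2) {
  stopifnot(length(id) == length(mate1), length(id) == length(mate2))
  if (any(!nzchar(mate1)) || any(!nzchar(mate2)))
    stop("read pairs must have non-empty mates")
  data.frame(id = as.character(id), mate1 = as.character(mate1),
             mate2 = as.character(mate2), stringsAsFactors = FALSE)
}

#' Per-locus multiple alignment
#'
#' The unit of contamination screening, treelikeness scoring and
#' concatenation: a set of equal-length aligned rows keyed by taxon.
#'
#' @param locus_id Locus label.
#' @param rows Named character vector, taxon -> aligned sequence.
#' @return Object of class `locus_aln`.
#' @export
locus_alignment <- function(locus_id, rows) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by taxon")
  if (anyDuplicated(names(rows)))
    stop("duplicate taxon in locus ", locus_id, ": ",
         names(rows)[duplicated(names(rows))][1L])
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("rows of locus ", locus_id, " differ in length")
  structure(list(locus_id = as.character(locus_id), rows = rows),
            class = "locus_aln")
}

#' @export
print.locus_aln <- function(x, ...) {
  cat("<locus_aln> ", x$locus_id, ": ", length(x$rows), " taxa x ",
      nchar(x$rows[[1L]]), " sites\n", sep = "")
  invisible(x)
}

#' Read a FASTA alignment as a `locus_aln`
#'
#' @param path FASTA file with equal-length rows.
#' @param locus_id Locus label; defaults to the file name without extension.
#' @export
read_alignment_fasta <- function(path, locus_id = NULL) {
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(path))
  locus_alignment(locus_id, read_fasta(path))
}

#' Taxon-group table
#'
#' Declares which taxa are presumed closely related; the contamination
#' screen only tests pairs drawn from different groups.
#'
#' @param assignment Named character vector, taxon -> group label.
#' @return Object of class `taxon_groups`.
#' @export
taxon_groups <- function(assignment) {
  stopifnot(is.character(assignment), length(assignment) >= 1L)
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("every taxon must appear exactly once")
  structure(list(assignment = assignment), class = "taxon_groups")
}

#' Read a taxon-group TSV (columns: taxon, group)
#' @param path TSV path with a header line.
#' @export
read_taxon_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df)))
    stop("groups table needs columns 'taxon' and 'group'")
  taxon_groups(setNames(as.character(df$group), df$taxon))
}

#' Write a taxon-group table as TSV
#' @param groups A [taxon_groups()] object.
#' @param path Output path.
#' @export
write_taxon_groups <- function(groups, path) {
  df <- data.frame(taxon = names(groups$assignment),
                   group = unname(groups$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read Newick trees (one or more per file)
#'
#' @param path Newick file, one tree per line allowed.
#' @return List of `phylo` objects (also for a single tree).
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' Write trees to Newick
#' @param trees A `phylo` or list of `phylo`.
#' @param path Output path.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, function(t) ape::write.tree(t), character(1L)), path)
  invisible(path)
}

aln_rows <- function(x) {
  if (inherits(x, "locus_aln")) x$rows
  else if (inherits(x, "supermatrix")) x$matrix
  else stop("expected a locus_aln or supermatrix")
}

#' Write an alignment or supermatrix as relaxed PHYLIP
#'
#' Relaxed PHYLIP: a "ntaxa nsites" header, then one line per taxon with
#' the whitespace-free name, a single space, and the full row.
#'
#' @param x A [locus_alignment()] or [concatenate()] result.
#' @param path Output path.
#' @export
write_phylip_relaxed <- function(x, path) {
  rows <- aln_rows(x)
  if (any(grepl("\\s", names(rows))))
    stop("taxon name contains whitespace: '",
         names(rows)[grepl("\\s", names(rows))][1L], "'")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(rows), nchar(rows[[1L]])), con)
  writeLines(paste(names(rows), unname(rows)), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#' @param path PHYLIP file written by [write_phylip_relaxed()].
#' @param locus_id Label for the returned alignment.
#' @return A `locus_aln`.
#' @export
read_phylip_relaxed <- function(path, locus_id = "phylip") {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hd <- as.integer(strsplit(trimws(ln[1L]), "\\s+")[[1L]])
  if (length(hd) != 2L || anyNA(hd)) stop("bad PHYLIP header in ", path)
  body <- ln[-1L]
  if (length(body) != hd[1L]) stop("expected ", hd[1L], " rows, got ", length(body))
  parts <- regmatches(body, regexpr("\\S+", body))
  seqs <- gsub("\\s", "", sub("^\\S+", "", body))
  if (any(nchar(seqs) != hd[2L])) stop("row length disagrees with header")
  locus_alignment(locus_id, setNames(seqs, parts))
}

# Normalize characters for analysis: uppercase; U -> T; '.' and '?' -> N;
# IUPAC ambiguity and anything unexpected -> N (undetermined). '-' kept.
norm_chars <- function(chars) {
  x <- toupper(chars)
  x[x == "U"] <- "T"
  x[!(x %in% c("A", "C", "G", "T", "-"))] <- "N"
  x
}

# Split aligned rows into an ntaxa x nsites character matrix.
aln_char_matrix <- function(rows, normalize = TRUE) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  if (normalize) m[] <- norm_chars(m)
  m
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(s))))
}
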