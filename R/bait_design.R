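#' Bait tiling parameters
#'
#' Defaults follow standard capture designs: 120-nt RNA baits tiled at
#' 2x density (60-nt overlap between consecutive baits).
#'
#' @param bait_length Bait length in nucleotides.
#' @param overlap Overlap between consecutive baits, nucleotides.
#' @export
bait_params <- function(bait_length = 120L, overlap = 60L) {
  bait_length <- as.integer(bait_length); overlap <- as.integer(overlap)
  if (!(overlap > 0L && overlap < bait_length))
    stop("need 0 < overlap < bait_length")
  structure(list(bait_length = bait_length, overlap = overlap),
            class = "bait_params")
}

#' Tile candidate baits across an exon
#'
#' The exon is right-padded with `N` to the smallest length `L >=
#' max(len, bait_length)` such that `L - bait_length` is divisible by the
#' step (`bait_length - overlap`); baits are cut at offsets `0, step,
#' 2*step, ...` so consecutive baits overlap by exactly `overlap` nt.
#' Pad `N`s are uppercase and therefore never count as soft-masked.
#'
#' @param exon A single named sequence (length-1 named character vector)
#'   or an unnamed string with `id` supplied.
#' @param params A [bait_params()] object.
#' @param id Locus id when `exon` is unnamed.
#' @return data.frame with columns `source_locus`, `start` (0-based
#'   offset on the padded exon), `seq`.
#' @export
tile_baits <- function(exon, params = bait_params(), id = NULL) {
  if (is.null(id)) id <- names(exon)
  if (is.null(id) || !nzchar(id)) stop("exon needs a locus id")
  s <- unname(exon[[1L]])
  if (!nzchar(s)) stop("empty exon ", id)
  bl <- params$bait_length
  step <- bl - params$overlap
  len <- nchar(s)
  n_baits <- 1L + as.integer(ceiling(max(0L, len - bl) / step))
  L <- bl + (n_baits - 1L) * step
  if (L > len) s <- paste0(s, strrep("N", L - len))
  starts <- (seq_len(n_baits) - 1L) * step
  data.frame(source_locus = id, start = starts,
             seq = substring(s, starts + 1L, starts + bl),
             stringsAsFactors = FALSE)
}

#' Tile baits over a whole exon set
#' @param exons Named character vector of exon sequences (one per locus).
#' @inheritParams tile_baits
#' @export
tile_baits_all <- function(exons, params = bait_params()) {
  do.call(rbind, lapply(names(exons), function(id)
    tile_baits(exons[id], params, id = id)))
}

#' Drop baits touching soft-masked sequence
#'
#' A bait is removed iff its sequence contains at least one lowercase
#' (soft-masked) character, anywhere. An optional maximum-N filter
#' (default off) additionally drops baits dominated by pad `N`s.
#'
#' @param baits data.frame from [tile_baits()].
#' @param max_n_frac Maximum tolerated fraction of `N` per bait; `1`
#'   disables the filter.
#' @return list with data.frames `kept` and `removed`.
#' @export
filter_softmasked <- function(baits, max_n_frac = 1) {
  if (is.null(baits) || nrow(baits) == 0L)
    return(list(kept = baits[0L, ], removed = baits[0L, ]))
  masked <- grepl("[a-z]", baits$seq)
  n_frac <- vapply(strsplit(toupper(baits$seq), "", fixed = TRUE),
                   function(ch) mean(ch == "N"), numeric(1L))
  drop <- masked | n_frac > max_n_frac
  list(kept = baits[!drop, , drop = FALSE],
       removed = baits[drop, , drop = FALSE])
}

#' Export a bait table as FASTA with `locus|start` headers
#' @param baits data.frame from [tile_baits()].
#' @param path Output path.
#' @export
write_baits_fasta <- function(baits, path) {
  write_fasta(setNames(baits$seq, paste0(baits$source_locus, "|", baits$start)),
              path)
}
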