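# Two-pass terminator search over search regions.
#
# The profile scorer is the primary detector; the descriptor is the fallback,
# consulted for a strand only when the profile yields no hit there.  All hit
# coordinates are mapped back to forward replicon coordinates with the strand
# recorded; on the "-" strand the stem5/loop/stem3/tail intervals still name
# the motif parts in transcript orientation, so the stem5 interval carries the
# larger forward coordinates.

# Map hits found on a scan-orientation sequence of width W back to forward
# replicon coordinates.  `lo` is the forward coordinate of scan position 1
# for "+", and of scan position W for "-".
#' @noRd
map_hits_to_forward <- function(h, lo, W, strand, replicon_id, rlen = NULL) {
  if (!nrow(h)) return(h)
  flip <- function(a, b) {
    # local [a,b] -> forward [lo + W - b, lo + W - a]
    list(start = lo + W - b, end = lo + W - a)
  }
  if (strand == "+") {
    for (col in c("stem5_start", "stem5_end", "loop_start", "loop_end",
                  "stem3_start", "stem3_end", "tail_start", "tail_end"))
      h[[col]] <- h[[col]] + lo - 1L
  } else {
    sw <- function(s, e) flip(s, e)
    a <- sw(h$stem5_start, h$stem5_end)
    h$stem5_start <- a$start; h$stem5_end <- a$end
    a <- sw(h$loop_start, h$loop_end)
    h$loop_start <- a$start; h$loop_end <- a$end
    a <- sw(h$stem3_start, h$stem3_end)
    h$stem3_start <- a$start; h$stem3_end <- a$end
    a <- sw(h$tail_start, h$tail_end)
    h$tail_start <- a$start; h$tail_end <- a$end
  }
  if (!is.null(rlen)) {  # wrap-around regions: fold back past the origin
    for (col in c("stem5_start", "stem5_end", "loop_start", "loop_end",
                  "stem3_start", "stem3_end", "tail_start", "tail_end"))
      h[[col]] <- (h[[col]] - 1L) %% rlen + 1L
  }
  h$strand <- strand
  h$replicon_id <- replicon_id
  h
}

#' Scan one search region on both strands (two-pass)
#'
#' Each strand of the region is scanned with the profile model when one is
#' supplied; if the profile finds no hit on a strand, the descriptor search
#' is run for that strand instead.  With `model = NULL` the behavior is pure
#' descriptor search.
#'
#' @param region A single-row slice of [extract_search_regions()] output.
#' @param ann The `genome_annotation` the region was derived from.
#' @param model A [train_profile()] model, or `NULL`.
#' @param params A [descriptor_params()] object.
#' @param energy An [default_energy_model()] object.
#' @return A hits data frame in forward replicon coordinates with `strand`,
#'   `region_id`, and flanking gene ids attached.
#' @export
scan_region <- function(region, ann, model = NULL,
                        params = descriptor_params(),
                        energy = default_energy_model()) {
  stopifnot(nrow(region) == 1)
  fwd <- region_sequence(region, ann)
  W <- nchar(fwd)
  rlen <- length(ann$replicons[[region$replicon_id]])
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else revcomp(fwd)
    h <- NULL
    if (!is.null(model)) {
      h <- scan_profile(s, model, params, energy)
      if (!nrow(h)) h <- NULL
    }
    if (is.null(h)) h <- scan_descriptor(s, params, energy)
    h <- map_hits_to_forward(h, region$lo, W, strand, region$replicon_id,
                             rlen = if (isTRUE(region$wrap)) rlen else NULL)
    out[[strand]] <- h
  }
  h <- rbind(out[["+"]], out[["-"]])
  if (nrow(h)) {
    h$region_id <- region$region_id
    h$left_gene_id <- region$left_gene_id
    h$right_gene_id <- region$right_gene_id
  } else {
    h$region_id <- character(0)
    h$left_gene_id <- character(0)
    h$right_gene_id <- character(0)
  }
  h
}

#' Scan all search regions of a genome
#'
#' @inheritParams scan_region
#' @param regions Output of [extract_search_regions()]; computed from `ann`
#'   when omitted.
#' @param short_orf_max Passed to [extract_search_regions()] when `regions`
#'   is omitted.
#' @return Combined hits data frame over all regions.
#' @export
scan_annotation <- function(ann, model = NULL, params = descriptor_params(),
                            energy = default_energy_model(), regions = NULL,
                            short_orf_max = 200L) {
  if (is.null(regions)) regions <- extract_search_regions(ann, short_orf_max)
  hits <- lapply(seq_len(nrow(regions)), function(i)
    scan_region(regions[i, , drop = FALSE], ann, model, params, energy))
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- empty_hits()
    out$region_id <- character(0)
    out$left_gene_id <- character(0)
    out$right_gene_id <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Write terminator hits as GFF3
#'
#' One `terminator` feature per hit, spanning stem 5' start to tail 3' end
#' (forward coordinates), with `stem_len`, `delta_g`, `score`, `method`,
#' `spacer_len` and `utr_class` attributes.
#'
#' @param hits A hits data frame (forward coordinates, strand set).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path) {
  lo <- pmin(hits$stem5_start, hits$tail_end)
  hi <- pmax(hits$stem5_start, hits$tail_end)
  gr <- GenomicRanges::GRanges(
    seqnames = hits$replicon_id,
    ranges = IRanges::IRanges(start = lo, end = hi),
    strand = hits$strand)
  S4Vectors::mcols(gr)$type <- "terminator"
  S4Vectors::mcols(gr)$stem_len <- hits$stem_len
  S4Vectors::mcols(gr)$delta_g <- hits$delta_g
  S4Vectors::mcols(gr)$score <- hits$score
  S4Vectors::mcols(gr)$method <- hits$method
  S4Vectors::mcols(gr)$spacer_len <- hits$spacer_len
  S4Vectors::mcols(gr)$utr_class <- hits$utr_class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
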