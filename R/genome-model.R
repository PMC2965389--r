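# Genomes, annotations and searchable intergenic regions.
#
# All user-facing coordinates are 1-based inclusive, forward-strand (GFF
# convention).  A genome_annotation bundles the replicon sequences with a
# sorted gene table; search regions are the maximal gaps between genes, into
# which short hypothetical ORFs (< 200 nt) are absorbed so that putative
# leader peptides are scanned rather than masked.

#' Construct a validated genome annotation
#'
#' @param species_id Species identifier.
#' @param replicons A named [Biostrings::DNAStringSet] (or named character
#'   vector) of replicon sequences.
#' @param genes A data frame with columns `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `product`; an optional logical
#'   `hypothetical` column is computed from `product` if absent.
#' @param topology Either a single value or a named vector over replicons,
#'   `"linear"` or `"circular"`.
#' @param hypothetical_patterns Case-insensitive regular expressions; a gene
#'   whose product matches any of them is flagged hypothetical.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(species_id, replicons, genes,
                              topology = "linear",
                              hypothetical_patterns = "hypothetical") {
  if (is.character(replicons))
    replicons <- Biostrings::DNAStringSet(normalize_sequence(replicons))
  stopifnot(methods::is(replicons, "DNAStringSet"),
            !is.null(names(replicons)), all(nzchar(names(replicons))))
  if (any(Biostrings::width(replicons) == 0))
    stop("replicon sequences must be non-empty")
  req <- c("gene_id", "replicon_id", "start", "end", "strand", "product")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("genes table lacks column(s): ",
                         paste(miss, collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (is.null(genes$hypothetical)) {
    pat <- paste(hypothetical_patterns, collapse = "|")
    genes$hypothetical <- grepl(pat, genes$product, ignore.case = TRUE)
  }
  genes$length <- genes$end - genes$start + 1L
  bad <- !genes$replicon_id %in% names(replicons)
  if (any(bad))
    stop("gene ", genes$gene_id[which(bad)[1]], " references unknown replicon ",
         genes$replicon_id[which(bad)[1]])
  rlen <- setNames(Biostrings::width(replicons), names(replicons))
  viol <- genes$start < 1L | genes$start > genes$end |
    genes$end > rlen[genes$replicon_id]
  if (any(viol))
    stop("gene ", genes$gene_id[which(viol)[1]],
         " has coordinates outside its replicon (or start > end)")
  if (length(topology) == 1L)
    topology <- setNames(rep(topology, length(replicons)), names(replicons))
  stopifnot(all(topology %in% c("linear", "circular")),
            all(names(replicons) %in% names(topology)))
  genes <- genes[order(genes$replicon_id, genes$start, genes$end,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(species_id = species_id, replicons = replicons,
                 topology = topology[names(replicons)], genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d replicon(s), %d genes, %s nt\n",
              x$species_id, length(x$replicons), nrow(x$genes),
              format(sum(Biostrings::width(x$replicons)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from FASTA and GFF3
#'
#' Replicon sequences are read with [Biostrings::readDNAStringSet()]
#' (lowercase and U are normalized to uppercase T); gene coordinates with
#' [rtracklayer::import()].  Rows of the requested feature types are turned
#' into gene records; the product is taken from the `product` (or `Note`)
#' attribute and genes are flagged hypothetical when the product matches
#' `hypothetical_patterns` (case-insensitive).
#'
#' @param fasta_path Path to a (multi-)FASTA of replicon sequences.
#' @param gff_path Path to a GFF3 annotation.
#' @param species_id Species identifier (defaults to the FASTA basename).
#' @param feature_types GFF3 feature types treated as genes; when both `gene`
#'   and `CDS` rows describe the same locus, `gene` rows win.
#' @inheritParams genome_annotation
#' @return A `genome_annotation`.
#' @export
read_genome <- function(fasta_path, gff_path,
                        species_id = sub("\\.[^.]*$", "", basename(fasta_path)),
                        feature_types = c("gene", "CDS"),
                        topology = "linear",
                        hypothetical_patterns = "hypothetical") {
  stopifnot(file.exists(fasta_path), file.exists(gff_path))
  reps <- Biostrings::readDNAStringSet(fasta_path)
  names(reps) <- sub("\\s.*$", "", names(reps))
  gr <- rtracklayer::import(gff_path)
  gr <- gr[as.character(gr$type) %in% feature_types]
  present <- feature_types[feature_types %in% as.character(gr$type)]
  if (length(present) > 1)  # prefer the first listed type (gene over CDS)
    gr <- gr[as.character(gr$type) == present[1]]
  md <- S4Vectors::mcols(gr)
  gid <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if ("locus_tag" %in% names(md))
    gid <- ifelse(is.na(gid), as.character(md$locus_tag), gid)
  if (anyNA(gid)) gid[is.na(gid)] <- paste0("gene", which(is.na(gid)))
  prod <- rep("", length(gr))
  for (col in c("product", "Note", "description"))
    if (col %in% names(md)) {
      v <- vapply(md[[col]], function(z) paste(unlist(z), collapse = "; "),
                  character(1))
      prod <- ifelse(nzchar(prod), prod, v)
    }
  genes <- data.frame(
    gene_id = gid,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = prod, stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene(s) without strand in GFF: ",
         paste(head(genes$gene_id[!genes$strand %in% c("+", "-")], 3),
               collapse = ", "))
  genome_annotation(species_id, reps, genes, topology = topology,
                    hypothetical_patterns = hypothetical_patterns)
}

#' Read a genome from FASTA plus a minimal TSV annotation
#'
#' The TSV dialect has columns `gene_id`, `replicon`, `start`, `end`,
#' `strand`, `product` (header required); coordinates are 1-based inclusive.
#'
#' @inheritParams read_genome
#' @param tsv_path Path to the annotation TSV.
#' @return A `genome_annotation`.
#' @export
read_annotation_tsv <- function(fasta_path, tsv_path,
                                species_id = sub("\\.[^.]*$", "",
                                                 basename(fasta_path)),
                                topology = "linear",
                                hypothetical_patterns = "hypothetical") {
  stopifnot(file.exists(fasta_path), file.exists(tsv_path))
  reps <- Biostrings::readDNAStringSet(fasta_path)
  names(reps) <- sub("\\s.*$", "", names(reps))
  tb <- read.delim(tsv_path, stringsAsFactors = FALSE, comment.char = "#")
  names(tb)[names(tb) == "replicon"] <- "replicon_id"
  genome_annotation(species_id, reps, tb, topology = topology,
                    hypothetical_patterns = hypothetical_patterns)
}

#' Derive searchable intergenic regions
#'
#' Emits one region per maximal gap between consecutive non-absorbed genes of
#' a replicon.  Hypothetical genes shorter than `short_orf_max` are absorbed:
#' they do not interrupt a gap and are recorded in `absorbed_orf_ids`.  For
#' linear replicons the stretches before the first and after the last gene
#' become regions with a missing flanking gene; circular replicons get a
#' single wrap-around region (whose `hi` coordinate may exceed the replicon
#' length by the amount wrapped past the origin).  Overlapping or abutting
#' genes yield no region.
#'
#' @param ann A `genome_annotation`.
#' @param short_orf_max Absorb hypothetical ORFs strictly shorter than this
#'   many nucleotides (default 200).
#' @return A data frame with columns `region_id`, `replicon_id`, `lo`, `hi`,
#'   `left_gene_id`, `right_gene_id` (NA at replicon ends),
#'   `absorbed_orf_ids` (comma-separated) and `wrap` (logical).
#' @export
extract_search_regions <- function(ann, short_orf_max = 200L) {
  stopifnot(inherits(ann, "genome_annotation"))
  out <- list()
  for (rep_id in names(ann$replicons)) {
    rlen <- Biostrings::width(ann$replicons[rep_id])
    g <- ann$genes[ann$genes$replicon_id == rep_id, , drop = FALSE]
    absorbed <- g$hypothetical & g$length < short_orf_max
    solid <- g[!absorbed, , drop = FALSE]
    sorf <- g[absorbed, , drop = FALSE]
    circular <- unname(ann$topology[rep_id]) == "circular"
    mk <- function(lo, hi, left, right, wrap = FALSE) {
      if (hi < lo) return(NULL)
      ids <- sorf$gene_id[sorf$start >= lo & sorf$end <= hi]
      list(replicon_id = rep_id, lo = lo, hi = hi,
           left_gene_id = left, right_gene_id = right,
           absorbed_orf_ids = paste(ids, collapse = ","), wrap = wrap)
    }
    if (!nrow(solid)) {
      out[[length(out) + 1L]] <- mk(1L, rlen, NA_character_, NA_character_)
      next
    }
    # merge overlapping solid genes into occupied blocks
    ends <- cummax(solid$end)
    is_new <- c(TRUE, solid$start[-1] > head(ends, -1))
    blk <- cumsum(is_new)
    b_lo <- tapply(solid$start, blk, min)
    b_hi <- tapply(solid$end, blk, max)
    b_left <- tapply(seq_len(nrow(solid)), blk, function(i)
      solid$gene_id[i[which.max(solid$end[i])]])   # gene ending the block
    b_right <- tapply(seq_len(nrow(solid)), blk, function(i)
      solid$gene_id[i[which.min(solid$start[i])]]) # gene starting the block
    nb <- length(b_lo)
    # interior gaps
    if (nb > 1)
      for (k in seq_len(nb - 1)) {
        lo <- b_hi[k] + 1L; hi <- b_lo[k + 1] - 1L
        out[[length(out) + 1L]] <- mk(lo, hi, b_left[[k]], b_right[[k + 1]])
      }
    if (!circular) {
      out[[length(out) + 1L]] <- mk(1L, b_lo[1] - 1L, NA_character_,
                                    b_right[[1]])
      out[[length(out) + 1L]] <- mk(b_hi[nb] + 1L, rlen, b_left[[nb]],
                                    NA_character_)
    } else {
      lo <- b_hi[nb] + 1L
      hi <- rlen + b_lo[1] - 1L
      if (hi >= lo) {
        ids <- sorf$gene_id[(sorf$start >= lo & sorf$end <= rlen) |
                              (sorf$end <= b_lo[1] - 1L)]
        out[[length(out) + 1L]] <- list(
          replicon_id = rep_id, lo = lo, hi = hi,
          left_gene_id = b_left[[nb]], right_gene_id = b_right[[1]],
          absorbed_orf_ids = paste(ids, collapse = ","), wrap = TRUE)
      }
    }
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(region_id = character(0), replicon_id = character(0),
                      lo = integer(0), hi = integer(0),
                      left_gene_id = character(0),
                      right_gene_id = character(0),
                      absorbed_orf_ids = character(0), wrap = logical(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(out, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  df <- df[order(df$replicon_id, df$lo), , drop = FALSE]
  df$region_id <- sprintf("%s:%d-%d", df$replicon_id, df$lo, df$hi)
  rownames(df) <- NULL
  df[, c("region_id", "replicon_id", "lo", "hi", "left_gene_id",
         "right_gene_id", "absorbed_orf_ids", "wrap")]
}

# Forward-strand sequence of a region (handles circular wrap-around).
#' @noRd
region_sequence <- function(region, ann) {
  rep_seq <- ann$replicons[[region$replicon_id]]
  rlen <- length(rep_seq)
  if (isTRUE(region$wrap) && region$hi > rlen) {
    paste0(as.character(Biostrings::subseq(rep_seq, region$lo, rlen)),
           as.character(Biostrings::subseq(rep_seq, 1L, region$hi - rlen)))
  } else {
    as.character(Biostrings::subseq(rep_seq, region$lo, region$hi))
  }
}

#' Write search regions as a BED-like TSV
#'
#' Columns are `replicon`, `lo`, `hi` (1-based inclusive, stated in the
#' header comment), flanking gene ids and absorbed ORFs.
#'
#' @param regions Output of [extract_search_regions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# search regions; coordinates are 1-based inclusive;",
                   "wrap regions extend past the replicon origin"), con)
  utils::write.table(regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
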