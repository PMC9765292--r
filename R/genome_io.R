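# Genome sequence + annotation container and I/O.
#
# All internal coordinates are 0-based half-open on the + strand; GFF3 I/O
# converts from/to the 1-based inclusive convention. Circular replicons are
# supported: a feature wrapping the origin is represented internally as two
# sub-intervals sharing one locus tag.

FEATURE_KINDS <- c("CDS", "rRNA", "tRNA", "intergenic")

.empty_features <- function() {
  data.frame(locus_tag = character(0), gene_name = character(0),
             kind = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct an annotated genome
#'
#' Container for a single replicon: its sequence, circularity flag and a
#' feature table (CDS, rRNA, tRNA, derived intergenic regions). Feature
#' coordinates are 0-based half-open; `start < end` always holds because a
#' feature wrapping the circular origin is stored as two rows with the same
#' `locus_tag`.
#'
#' @param id replicon identifier.
#' @param sequence DNA string over `A,C,G,T,N` (lowercase accepted, uppercased).
#' @param circular logical; is the replicon circular?
#' @param features data.frame with columns `locus_tag`, `gene_name`, `kind`,
#'   `strand`, `start`, `end`, or `NULL` for none.
#' @return an object of class `annotated_genome` with fields `id`, `sequence`,
#'   `circular`, `length`, `features`.
#' @export
annotated_genome <- function(id, sequence, circular = TRUE, features = NULL) {
  sequence <- .validate_dna(sequence, "genome sequence")
  if (is.null(features) || nrow(features) == 0L) features <- .empty_features()
  needed <- c("locus_tag", "gene_name", "kind", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  features <- features[needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  L <- nchar(sequence)
  if (nrow(features)) {
    if (any(features$start < 0L) || any(features$end > L)) {
      stop("feature coordinates beyond sequence length", call. = FALSE)
    }
    if (any(features$start >= features$end)) {
      stop("features must satisfy start < end (wrap = two sub-intervals)",
           call. = FALSE)
    }
    if (!all(features$kind %in% FEATURE_KINDS)) {
      stop("unknown feature kind(s): ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "),
           call. = FALSE)
    }
    if (any(features$kind == "intergenic" & features$strand != "both")) {
      stop("intergenic features must have strand 'both'", call. = FALSE)
    }
    rownames(features) <- NULL
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), length = L, features = features),
    class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d feature row(s)\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features)) {
    print(table(x$features$kind))
  }
  invisible(x)
}

#' Read a genome from FASTA + GFF3
#'
#' Loads a single-replicon FASTA and (optionally) its GFF3 annotation.
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention. Only `CDS`, `rRNA` and `tRNA` features are
#' loaded; other feature types are skipped with a warning.
#'
#' @param fasta_path path to a FASTA file with exactly one record.
#' @param gff_path path to a GFF3 file, or `NULL` for an unannotated genome.
#' @param circular logical; treat the replicon as circular?
#' @return an [annotated_genome()].
#' @export
read_genome <- function(fasta_path, gff_path = NULL, circular = TRUE) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record, found ", length(seqs), call. = FALSE)
  }
  id <- sub("\\s.*$", "", names(seqs)[1L])
  sequence <- toupper(as.character(seqs[[1L]]))
  features <- .empty_features()
  if (!is.null(gff_path)) {
    if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path, call. = FALSE)
    features <- .read_gff3_features(gff_path, nchar(sequence))
  }
  annotated_genome(id, sequence, circular, features)
}

#' @keywords internal
#' @noRd
.read_gff3_features <- function(gff_path, genome_length) {
  lines <- readLines(gff_path, warn = FALSE)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(body)) return(.empty_features())
  gr <- rtracklayer::import(gff_path, format = "gff3")
  kind <- as.character(gr$type)
  keep <- kind %in% c("CDS", "rRNA", "tRNA")
  if (any(!keep)) {
    warning("ignoring ", sum(!keep), " feature(s) of unknown kind(s): ",
            paste(unique(kind[!keep]), collapse = ", "), call. = FALSE)
    gr <- gr[keep]
    kind <- kind[keep]
  }
  if (!length(gr)) return(.empty_features())
  mc <- S4Vectors::mcols(gr)
  tag <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag) else NA_character_
  if (all(is.na(tag)) && "ID" %in% names(mc)) tag <- as.character(mc$ID)
  if (any(is.na(tag))) {
    stop("GFF3 features lack locus_tag/ID attributes", call. = FALSE)
  }
  if (anyDuplicated(tag)) {
    stop("duplicate feature identifiers in GFF3: ",
         paste(unique(tag[duplicated(tag)]), collapse = ", "), call. = FALSE)
  }
  gene <- if ("gene" %in% names(mc)) as.character(mc$gene) else NA_character_
  st <- as.character(BiocGenerics::strand(gr))
  if (any(!st %in% c("+", "-"))) {
    stop("annotated features must be stranded (+/-)", call. = FALSE)
  }
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(start0 < 0L) || any(end0 > genome_length)) {
    stop("feature coordinates beyond sequence length", call. = FALSE)
  }
  data.frame(locus_tag = tag, gene_name = gene, kind = kind, strand = st,
             start = start0, end = end0, stringsAsFactors = FALSE)
}

#' Write a genome to FASTA (+ GFF3)
#'
#' Inverse of [read_genome()]: the FASTA body round-trips byte-identically
#' (sequence content) and the annotated feature set is preserved. Derived
#' intergenic features are not written (they are re-derivable).
#'
#' @param genome an [annotated_genome()].
#' @param fasta_path output FASTA path.
#' @param gff_path output GFF3 path, or `NULL` to skip annotation.
#' @return invisibly, a list of the written paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, fasta_path)
  if (!is.null(gff_path)) {
    f <- genome$features[genome$features$kind != "intergenic", , drop = FALSE]
    con <- file(gff_path, open = "wt")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(sprintf("##sequence-region %s 1 %d", genome$id, genome$length), con)
    if (nrow(f)) {
      attr_col <- sprintf("ID=%s;locus_tag=%s%s", f$locus_tag, f$locus_tag,
                          ifelse(is.na(f$gene_name), "",
                                 paste0(";gene=", f$gene_name)))
      writeLines(paste(genome$id, "crispriscreen", f$kind,
                       f$start + 1L, f$end, ".", f$strand, ".", attr_col,
                       sep = "\t"), con)
    }
  }
  invisible(list(fasta = fasta_path, gff = gff_path))
}

#' Derive intergenic regions
#'
#' Computes the maximal gaps left uncovered by the union of annotated
#' (non-intergenic) feature intervals. Gaps are emitted with
#' `kind = "intergenic"` and `strand = "both"`. On a circular genome a gap
#' spanning the origin is one region, represented as two rows sharing a
#' locus tag; `min_length` applies to its combined length.
#'
#' @param genome an [annotated_genome()].
#' @param min_length minimum gap length in bp to keep (default 1 = keep all).
#' @return data.frame of intergenic features (possibly empty).
#' @export
derive_intergenic <- function(genome, min_length = 1L) {
  stopifnot(inherits(genome, "annotated_genome"), min_length >= 1L)
  L <- genome$length
  f <- genome$features[genome$features$kind != "intergenic", , drop = FALSE]
  if (L == 0L) return(.empty_features())
  mk <- function(tag, start, end) {
    data.frame(locus_tag = tag, gene_name = NA_character_,
               kind = "intergenic", strand = "both",
               start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }
  if (nrow(f) == 0L) {
    if (L < min_length) return(.empty_features())
    return(mk("IG_0001", 0L, L))
  }
  ir <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  if (!length(gaps)) return(.empty_features())
  gs <- BiocGenerics::start(gaps) - 1L
  ge <- BiocGenerics::end(gaps)
  glen <- ge - gs
  # circular wraparound: the head gap [0, .) and tail gap [., L) form one region
  wrap_pair <- genome$circular && length(gaps) >= 2L &&
    gs[1L] == 0L && ge[length(gaps)] == L
  region_id <- seq_along(gs)
  if (wrap_pair) region_id[length(gs)] <- region_id[1L]
  region_len <- tapply(glen, region_id, sum)
  keep_regions <- as.integer(names(region_len))[region_len >= min_length]
  keep <- region_id %in% keep_regions
  if (!any(keep)) return(.empty_features())
  gs <- gs[keep]; ge <- ge[keep]; region_id <- region_id[keep]
  tag <- sprintf("IG_%04d", match(region_id, unique(region_id)))
  mk(tag, gs, ge)
}

#' Attach derived intergenic regions to a genome
#'
#' Convenience wrapper: returns the genome with intergenic features appended
#' to its feature table.
#'
#' @inheritParams derive_intergenic
#' @return an [annotated_genome()] including intergenic features.
#' @export
annotate_intergenic <- function(genome, min_length = 1L) {
  ig <- derive_intergenic(genome, min_length)
  f <- genome$features[genome$features$kind != "intergenic", , drop = FALSE]
  annotated_genome(genome$id, genome$sequence, genome$circular, rbind(f, ig))
}
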