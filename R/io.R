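#' Read a bedGraph coverage file into a dense track
#'
#' bedGraph intervals are 0-based half-open; positions absent from the file
#' are zero. Parsing goes through [rtracklayer::import()].
#'
#' @param path bedGraph file.
#' @param replicon_length Length of the replicon in nt.
#' @param strand `"+"` or `"-"` (one file per strand).
#' @param library_total Total mapped reads for this library; if `NULL`, it is
#'   looked up in `library_sizes` under `library_id`.
#' @param library_sizes Optional named numeric vector from
#'   [read_library_sizes()].
#' @param library_id Key into `library_sizes`; defaults to the file base name
#'   without extension.
#' @param replicon_id Replicon name recorded on the track.
#' @return A raw [coverage_track()].
#' @export
read_bedgraph <- function(path, replicon_length, strand,
                          library_total = NULL, library_sizes = NULL,
                          library_id = NULL, replicon_id = "chr") {
  replicon_length <- as.integer(replicon_length)
  values <- numeric(replicon_length)
  nonempty <- file.exists(path) && any(nzchar(trimws(readLines(path, warn = FALSE))))
  if (nonempty) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr)) {
      score <- as.numeric(S4Vectors::mcols(gr)$score)
      if (any(is.na(score))) stopf("%s: missing coverage values", path)
      if (any(score < 0)) stopf("%s: negative coverage values", path)
      s <- GenomicRanges::start(gr) - 1L  # to 0-based half-open
      e <- GenomicRanges::end(gr)
      if (any(e > replicon_length)) stopf("%s: interval beyond replicon end", path)
      hits <- IRanges::findOverlaps(IRanges::IRanges(s + 1L, e), drop.self = TRUE)
      if (length(hits)) {
        i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
        if (any(score[i] != score[j])) {
          stopf("%s: overlapping intervals with conflicting values", path)
        }
      }
      for (k in seq_along(s)) values[(s[k] + 1L):e[k]] <- score[k]
    }
  }
  if (is.null(library_total)) {
    if (is.null(library_sizes)) stopf("supply library_total or library_sizes")
    library_id <- library_id %||% tools::file_path_sans_ext(basename(path))
    if (!library_id %in% names(library_sizes)) {
      stopf("library '%s' not in library_sizes", library_id)
    }
    library_total <- library_sizes[[library_id]]
  }
  coverage_track(values, strand = strand, replicon_id = replicon_id,
                 library_total = library_total)
}

#' Write a coverage track as 4-column bedGraph
#'
#' Consecutive equal values are run-length collapsed; zero runs are omitted.
#'
#' @param track A [coverage_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  end <- cumsum(r$lengths)
  start <- end - r$lengths  # 0-based half-open
  keep <- r$values != 0
  df <- data.frame(chrom = track$replicon_id, start = start[keep],
                   end = end[keep], value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the per-library mapped-read totals sidecar
#'
#' Two-column TSV: `library_id`, `mapped_reads`.
#' @param path TSV file.
#' @return Named numeric vector of totals.
#' @export
read_library_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$mapped_reads), df$library_id)
}

#' @rdname read_library_sizes
#' @param sizes Named numeric vector of totals.
#' @export
write_library_sizes <- function(sizes, path) {
  df <- data.frame(library_id = names(sizes), mapped_reads = as.numeric(sizes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts `gene` features with `CDS`, `five_prime_UTR` and `three_prime_UTR`
#' children linked by `Parent` (or sharing the gene's `ID`). GFF3 1-based
#' inclusive coordinates are converted to internal 0-based half-open. UTRs
#' must abut the CDS on the side their kind implies for the gene's strand;
#' genes lacking a CDS are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return Gene model data frame (one row per gene; see [gene_model()]).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  gene_idx <- which(type == "gene")
  out <- vector("list", length(gene_idx))
  for (g in seq_along(gene_idx)) {
    i <- gene_idx[g]
    gid <- ids[i]
    child <- which(parents == gid | (ids == gid & type != "gene"))
    ctype <- type[child]
    cds <- child[ctype == "CDS"]
    if (!length(cds)) {
      warnf("gene %s has no CDS feature; skipped", gid)
      next
    }
    cds_start <- min(GenomicRanges::start(gr[cds])) - 1L
    cds_end <- max(GenomicRanges::end(gr[cds]))
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-")) stopf("gene %s: missing strand", gid)
    u5 <- child[ctype == "five_prime_UTR"]
    u3 <- child[ctype == "three_prime_UTR"]
    utr5_len <- if (length(u5)) sum(GenomicRanges::width(gr[u5])) else 0L
    utr3_len <- if (length(u3)) sum(GenomicRanges::width(gr[u3])) else 0L
    check_abut <- function(idx, side5prime) {
      if (!length(idx)) return(invisible())
      us <- min(GenomicRanges::start(gr[idx])) - 1L
      ue <- max(GenomicRanges::end(gr[idx]))
      upstream <- (side5prime && strand == "+") || (!side5prime && strand == "-")
      ok <- if (upstream) ue == cds_start else us == cds_end
      if (!ok) stopf("gene %s: UTR does not abut the CDS (utr_not_abutting)", gid)
    }
    check_abut(u5, TRUE); check_abut(u3, FALSE)
    out[[g]] <- gene_model(gid, cds_start, cds_end, strand,
                           utr5_len = utr5_len, utr3_len = utr3_len,
                           replicon_id = as.character(GenomicRanges::seqnames(gr[i])))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_gene_table())
  do.call(rbind, out)
}

empty_gene_table <- function() {
  data.frame(id = character(), replicon_id = character(), strand = character(),
             start = integer(), end = integer(), cds_start = integer(),
             cds_end = integer(), utr5_len = integer(), utr3_len = integer(),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `CDS` and UTR features (1-based inclusive) with `ID`/`Parent`
#' links, via [rtracklayer::export()].
#'
#' @param genes Gene model data frame.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list(); n <- 0L
  add <- function(replicon, start0, end0, type, id, parent = NA_character_, strand) {
    n <<- n + 1L
    rows[[n]] <<- data.frame(replicon = replicon, start = start0 + 1L, end = end0,
                             type = type, ID = id, Parent = parent, strand = strand,
                             stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    add(g$replicon_id, g$start, g$end, "gene", g$id, NA_character_, g$strand)
    add(g$replicon_id, g$cds_start, g$cds_end, "CDS",
        paste0(g$id, ".cds"), g$id, g$strand)
    up_len <- if (g$strand == "+") g$utr5_len else g$utr3_len
    dn_len <- if (g$strand == "+") g$utr3_len else g$utr5_len
    up_type <- if (g$strand == "+") "five_prime_UTR" else "three_prime_UTR"
    dn_type <- if (g$strand == "+") "three_prime_UTR" else "five_prime_UTR"
    if (up_len > 0) add(g$replicon_id, g$start, g$cds_start,
                        up_type, paste0(g$id, ".u5"), g$id, g$strand)
    if (dn_len > 0) add(g$replicon_id, g$cds_end, g$end,
                        dn_type, paste0(g$id, ".u3"), g$id, g$strand)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$replicon,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write genome FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read / write mapped transcript end sites
#'
#' TSV with columns `replicon_id`, `strand`, `position` (0-based position of
#' the terminal nucleotide) and `kind` (`five_prime` or `three_prime`).
#' @param path TSV file.
#' @return Data frame of end sites.
#' @export
read_end_sites <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("replicon_id", "strand", "position", "kind")
  if (!all(need %in% names(df))) stopf("end-site file must have columns %s",
                                       paste(need, collapse = ", "))
  if (!all(df$kind %in% c("five_prime", "three_prime"))) {
    stopf("end-site kind must be five_prime or three_prime")
  }
  df
}

#' @rdname read_end_sites
#' @param sites End-site data frame.
#' @export
write_end_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a decRNA catalog as TSV (and optionally BED6)
#'
#' Column layout mirrors a catalog table: host gene, coordinates, length,
#' replicate support, percent CDS overlap, category, sequence and (when
#' present) predicted per-nucleotide fold stability.
#'
#' @param calls decRNA call data frame from [detect_decrnas()].
#' @param path Output TSV.
#' @param bed_path Optional BED6 output.
#' @export
write_catalog <- function(calls, path, bed_path = NULL) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = calls$replicon_id, start = calls$start,
                      end = calls$end, name = calls$id,
                      score = calls$n_replicates_support, strand = calls$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
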