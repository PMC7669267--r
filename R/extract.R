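# Read-level variant extraction: demultiplex -> locate gene -> NNK filters.

REJECTION_REASONS <- c("barcode_unmatched", "length_error", "anchor_not_found",
                       "filter_a_non_nnk", "filter_b_nonsynonymous_offtarget")

asCharacterReads <- function(reads) {
  if (is(reads, "DNAStringSet")) as.character(reads) else as.character(reads)
}

#' Demultiplex reads by exact barcode match
#'
#' Assigns each read to at most one sample by exact match of its leading
#' `barcodeLength` bases against the template's barcode map. The assignment
#' is a partition: per-sample counts plus the unmatched count equal the
#' input read count.
#'
#' @param reads Character vector or `DNAStringSet` of reads (barcode first).
#' @param template A [TemplateSpec-class] with a non-empty barcode map.
#' @return List with `samples` (named list of barcode-stripped reads per
#'   sample id) and `unmatched` (integer count).
#' @export
demultiplexReads <- function(reads, template) {
  stopifnot(is(template, "TemplateSpec"))
  map <- barcodeMap(template)
  if (!length(map)) stop("template has an empty barcode map")
  reads <- asCharacterReads(reads)
  bl <- template@barcodeLength
  idx <- match(substr(reads, 1L, bl), names(map))
  stripped <- substr(reads, bl + 1L, nchar(reads))
  samples <- lapply(unique(unname(map)), function(sid) {
    stripped[!is.na(idx) & unname(map)[idx] == sid]
  })
  names(samples) <- unique(unname(map))
  list(samples = samples, unmatched = sum(is.na(idx)))
}

#' Parse barcode-stripped reads into variant calls
#'
#' Implements the two library filters after locating the gene: the gene is
#' found by exact match of the anchor (first `anchorLength` gene bases) at
#' each admissible spacer offset, in order. A read is rejected with
#' `filter_a_non_nnk` if any randomised codon violates the NNK pattern
#' (third base G/T; ambiguity characters also reject), and with
#' `filter_b_nonsynonymous_offtarget` if any non-randomised codon encodes a
#' residue different from the wild type (synonymous changes pass). Each
#' rejected read carries the first failing check in the order
#' length -> anchor -> (a) -> (b).
#'
#' @param seqs Character vector of barcode-stripped reads.
#' @param template A [TemplateSpec-class].
#' @return List with `accepted` (`data.frame` of `codon_triplet`,
#'   `aa_triplet` for accepted reads) and `reason` (character vector, `NA`
#'   for accepted reads).
#' @export
parseReads <- function(seqs, template) {
  stopifnot(is(template, "TemplateSpec"))
  seqs <- asCharacterReads(seqs)
  n <- length(seqs)
  geneLen <- nchar(geneSeq(template))
  k <- template@anchorLength
  anchor <- substr(geneSeq(template), 1L, k)
  sp <- template@spacerRange
  reason <- rep(NA_character_, n)
  reason[nchar(seqs) < sp[1] + geneLen] <- "length_error"

  offset <- rep(NA_integer_, n)
  for (off in seq(sp[1], sp[2])) {
    cand <- is.na(reason) & is.na(offset) & nchar(seqs) >= off + geneLen &
      substr(seqs, off + 1L, off + k) == anchor
    offset[cand] <- off
  }
  reason[is.na(reason) & is.na(offset)] <- "anchor_not_found"

  ok <- is.na(reason)
  gene <- substr(seqs[ok], offset[ok] + 1L, offset[ok] + geneLen)
  ncod <- nCodons(template)
  cm <- codonMatrix(gene, ncod)
  if (length(gene) == 1L) cm <- matrix(cm, nrow = 1L)
  rp <- codonPositions(template)

  # filter (a): NNK pattern at the randomised codons
  nnkOk <- rep(TRUE, length(gene))
  for (p in rp) nnkOk <- nnkOk & grepl("^[ACGT][ACGT][GT]$", cm[, p])

  # filter (b): off-target codons must translate to the wild-type residue
  wt <- strsplit(wtProtein(template), "")[[1]]
  others <- setdiff(seq_len(ncod), rp)
  synOk <- rep(TRUE, length(gene))
  for (p in others) {
    aa <- translateCodons(cm[, p])
    synOk <- synOk & !is.na(aa) & aa == wt[p]
  }

  r <- rep(NA_character_, length(gene))
  r[!nnkOk] <- "filter_a_non_nnk"
  r[nnkOk & !synOk] <- "filter_b_nonsynonymous_offtarget"
  reason[ok] <- r

  acc <- is.na(r)
  codTrip <- paste0(cm[acc, rp[1]], cm[acc, rp[2]], cm[acc, rp[3]])
  aaTrip <- vapply(seq_along(codTrip), function(i)
    paste(translateCodons(substring(codTrip[i], c(1, 4, 7), c(3, 6, 9))),
          collapse = ""), "")
  list(accepted = data.frame(codon_triplet = codTrip, aa_triplet = aaTrip,
                             stringsAsFactors = FALSE),
       reason = reason)
}

#' Tally accepted variant calls into codon-level counts
#'
#' @param accepted `data.frame` from [parseReads()]`$accepted` for one
#'   sample.
#' @return `data.frame` with `codon_triplet`, `aa_triplet`, `reads`; total
#'   reads equal the number of accepted calls.
#' @export
countVariants <- function(accepted) {
  if (!nrow(accepted))
    return(data.frame(codon_triplet = character(), aa_triplet = character(),
                      reads = integer(), stringsAsFactors = FALSE))
  tab <- table(accepted$codon_triplet)
  aa <- accepted$aa_triplet[match(names(tab), accepted$codon_triplet)]
  data.frame(codon_triplet = names(tab), aa_triplet = aa,
             reads = as.integer(tab), stringsAsFactors = FALSE)
}

#' Extract variant counts from multiplexed reads
#'
#' Full read-to-counts path: demultiplex by barcode, parse each sample's
#' reads through the NNK and off-target filters, and tabulate codon-level
#' counts into one [SelectionCounts-class] object. Rejection reasons per
#' sample are kept in `metadata()$rejections`.
#'
#' @param reads Character vector, `DNAStringSet`, or path to a FASTQ file
#'   (optionally gzipped) of multiplexed reads.
#' @param template A [TemplateSpec-class] with barcode map.
#' @param sampleInfo `data.frame` with columns `sample_id`, `toxin`,
#'   `replicate`, `timepoint` covering the sample ids in the barcode map.
#' @param level Return `"codon"`-level counts (default) or aggregate to
#'   `"protein"`.
#' @return A [SelectionCounts-class] object.
#' @export
extractVariants <- function(reads, template, sampleInfo,
                            level = c("codon", "protein")) {
  level <- match.arg(level)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  dm <- demultiplexReads(reads, template)
  sids <- names(dm$samples)
  missing <- setdiff(sids, sampleInfo$sample_id)
  if (length(missing))
    stop("sampleInfo lacks rows for: ", paste(missing, collapse = ", "))
  parsed <- lapply(dm$samples, parseReads, template = template)
  tabs <- lapply(parsed, function(p) countVariants(p$accepted))
  allTrip <- sort(unique(unlist(lapply(tabs, `[[`, "codon_triplet"))))
  m <- matrix(0L, length(allTrip), length(sids),
              dimnames = list(allTrip, sids))
  for (s in sids) {
    t <- tabs[[s]]
    m[t$codon_triplet, s] <- t$reads
  }
  si <- sampleInfo[match(sids, sampleInfo$sample_id), , drop = FALSE]
  sc <- SelectionCounts(m, si, level = "codon",
                        reference = wtTriplet(template))
  S4Vectors::metadata(sc)$rejections <- lapply(parsed, function(p) {
    tab <- table(factor(p$reason, levels = REJECTION_REASONS))
    c(as.list(tab), list(accepted = sum(is.na(p$reason))))
  })
  S4Vectors::metadata(sc)$unmatched <- dm$unmatched
  if (level == "protein") sc <- aggregateToProtein(sc)
  sc
}

#' Read/write count tables as TSV
#'
#' Long-format TSV with columns `sample_id`, `toxin`, `replicate`,
#' `timepoint`, `aa_triplet`, `codon_triplet` (protein level: `NA`), `reads`.
#'
#' @param x A [SelectionCounts-class] object.
#' @param path Output file.
#' @return `writeCountsTsv` returns `path` invisibly; `readCountsTsv`
#'   returns a [SelectionCounts-class].
#' @export
writeCountsTsv <- function(x, path) {
  m <- readCountMatrix(x)
  rd <- SummarizedExperiment::rowData(x)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  long <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    keep <- m[, j] > 0L
    data.frame(sample_id = cd$sample_id[j], toxin = cd$toxin[j],
               replicate = cd$replicate[j], timepoint = cd$timepoint[j],
               aa_triplet = rd$aa_triplet[keep],
               codon_triplet = if ("codon_triplet" %in% colnames(rd))
                 rd$codon_triplet[keep] else NA_character_,
               reads = m[keep, j], stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @param reference Reference triplet recorded in the rebuilt object.
#' @export
readCountsTsv <- function(path, reference = "DKE") {
  long <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(codon_triplet = "character"))
  level <- if (all(is.na(long$codon_triplet)) ||
               !nzchar(long$codon_triplet[1])) "protein" else "codon"
  key <- if (level == "codon") long$codon_triplet else long$aa_triplet
  sids <- unique(long$sample_id)
  trips <- sort(unique(key))
  m <- matrix(0L, length(trips), length(sids), dimnames = list(trips, sids))
  m[cbind(match(key, trips), match(long$sample_id, sids))] <-
    as.integer(long$reads)
  si <- unique(long[, c("sample_id", "toxin", "replicate", "timepoint")])
  si <- si[match(sids, si$sample_id), , drop = FALSE]
  SelectionCounts(m, si, level = level, reference = reference)
}

#' Read a template specification from YAML
#'
#' Expected keys: `gene_nt`, `randomized_codon_positions` (1-based),
#' `barcode_map` (mapping barcode -> sample id), and optionally
#' `spacer_range`, `anchor_length`, `barcode_length`.
#'
#' @param path YAML file path.
#' @return A [TemplateSpec-class].
#' @export
readTemplateYaml <- function(path) {
  y <- yaml::read_yaml(path)
  TemplateSpec(y$gene_nt,
               as.integer(y$randomized_codon_positions),
               barcodeMap = unlist(y$barcode_map),
               barcodeLength = y$barcode_length,
               spacerRange = if (!is.null(y$spacer_range))
                 as.integer(y$spacer_range) else c(4L, 6L),
               anchorLength = if (!is.null(y$anchor_length))
                 as.integer(y$anchor_length) else 12L)
}
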