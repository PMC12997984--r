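#' Construct a per-base depth profile
#'
#' @param target_id Reference identifier (a MAG, a 16S gene, or a CDS).
#' @param depth Non-negative integer vector of per-base read depth, one entry
#'   per reference base.
#' @param mapped_read_count Number of mapped reads (needed for relative
#'   abundance); optional.
#' @param mean_read_identity Mean alignment identity of the mapped reads in
#'   `[0, 1]`; optional, required only when an identity rule is applied.
#' @return An object of class `depth_profile`. `mapped_read_bases` is the sum
#'   of the depth vector (every mapped base contributes one depth unit).
#' @export
depth_profile <- function(target_id, depth, mapped_read_count = NA_integer_,
                          mean_read_identity = NA_real_) {
  if (length(depth) == 0L) stop("target length must be positive")
  if (any(depth < 0)) stop("depth must be non-negative")
  structure(list(target_id = target_id, length = length(depth),
                 depth = as.numeric(depth),
                 mapped_read_count = mapped_read_count,
                 mapped_read_bases = sum(depth),
                 mean_read_identity = mean_read_identity),
            class = "depth_profile")
}

#' Read depth profiles from a per-base depth table
#'
#' The table is the `samtools depth -a` dialect: columns `target`, `pos`
#' (1-based), `depth`, with every position of every target present.
#'
#' @param path TSV path (no header, or header `target pos depth`).
#' @return Named list of `depth_profile` objects.
#' @export
read_depth_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("target", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(tab) <- c("target", "pos", "depth")
  out <- lapply(split(tab, tab$target), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (!identical(d$pos, seq_len(nrow(d)))) {
      stop("depth table for ", d$target[1],
           " is not a dense 1..L position vector")
    }
    depth_profile(d$target[1], d$depth)
  })
  out[unique(tab$target)]
}

#' Build depth profiles from a sorted, indexed BAM file
#'
#' Uses `Rsamtools::pileup` over primary, non-supplementary alignments with a
#' configurable mapping-quality floor. Targets absent from the BAM yield
#' all-zero profiles.
#'
#' @param bam Path to a sorted BAM with an index.
#' @param target_lengths Named integer vector of reference lengths.
#' @param min_mapq Mapping-quality floor (default 0).
#' @return Named list of `depth_profile` objects.
#' @export
depth_from_bam <- function(bam, target_lengths, min_mapq = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("depth_from_bam requires the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  pparam <- Rsamtools::PileupParam(max_depth = 1e6, min_base_quality = 0L,
                                   min_mapq = min_mapq,
                                   distinguish_strands = FALSE,
                                   distinguish_nucleotides = FALSE)
  pil <- Rsamtools::pileup(bam,
                           scanBamParam = Rsamtools::ScanBamParam(flag = flag),
                           pileupParam = pparam)
  idx <- Rsamtools::idxstatsBam(bam)
  out <- lapply(names(target_lengths), function(tg) {
    depth <- numeric(target_lengths[[tg]])
    rows <- pil[pil$seqnames == tg, , drop = FALSE]
    depth[rows$pos] <- rows$count
    nreads <- as.integer(sum(idx$mapped[idx$seqnames == tg]))
    depth_profile(tg, depth, mapped_read_count = nreads)
  })
  stats::setNames(out, names(target_lengths))
}

#' Breadth of coverage
#'
#' Fraction of reference bases with at least one mapped read.
#'
#' @param p A `depth_profile`.
#' @return Numeric in `[0, 1]`.
#' @export
breadth_of_coverage <- function(p) {
  stopifnot(inherits(p, "depth_profile"), p$length > 0)
  sum(p$depth >= 1) / p$length
}

#' Average read depth
#'
#' Total length of all mapped reads divided by the reference length;
#' identical to the mean of the per-base depth vector when depth derives
#' from full read placements.
#'
#' @param p A `depth_profile`.
#' @return Non-negative numeric.
#' @export
average_read_depth <- function(p) {
  stopifnot(inherits(p, "depth_profile"), p$length > 0)
  p$mapped_read_bases / p$length
}

#' Relative abundance of a target in a sample
#'
#' @param mapped_read_count Reads mapped to the target.
#' @param total_sample_reads All reads in the sample (must be positive).
#' @return Numeric in `[0, 1]`.
#' @export
relative_abundance <- function(mapped_read_count, total_sample_reads) {
  if (any(total_sample_reads <= 0)) stop("total_sample_reads must be positive")
  stopifnot(all(mapped_read_count >= 0),
            all(mapped_read_count <= total_sample_reads))
  mapped_read_count / total_sample_reads
}

#' Call presence of a target in a sample
#'
#' A target is present when `BC >= bc_min` and `ARD >= ard_min` (both
#' inclusive; defaults 0.6 and 1). When `identity_min` is supplied — the rule
#' used for 16S markers — the profile's mean read identity must additionally
#' exceed it (strict `>`).
#'
#' @param p A `depth_profile`.
#' @param sample_id Sample identifier.
#' @param total_sample_reads Total reads in the sample (for relative
#'   abundance); optional.
#' @param bc_min,ard_min Inclusive thresholds on breadth of coverage and
#'   average read depth.
#' @param identity_min Optional exclusive threshold on mean read identity.
#' @return One-row `data.frame`: `sample_id`, `target_id`, `bc`, `ard`,
#'   `relative_abundance`, `present`.
#' @export
call_presence <- function(p, sample_id = NA_character_,
                          total_sample_reads = NA_real_,
                          bc_min = 0.6, ard_min = 1.0, identity_min = NULL) {
  bc <- breadth_of_coverage(p)
  ard <- average_read_depth(p)
  present <- bc >= bc_min && ard >= ard_min
  if (!is.null(identity_min)) {
    if (is.na(p$mean_read_identity)) {
      stop("identity_min supplied but profile has no mean_read_identity")
    }
    present <- present && p$mean_read_identity > identity_min
  }
  ra <- if (!is.na(total_sample_reads) && !is.na(p$mapped_read_count)) {
    relative_abundance(p$mapped_read_count, total_sample_reads)
  } else NA_real_
  data.frame(sample_id = sample_id, target_id = p$target_id,
             bc = bc, ard = ard, relative_abundance = ra,
             present = present, stringsAsFactors = FALSE)
}

#' Cohort prevalence from presence calls
#'
#' A sample is positive when at least one target is present in it. Prevalence
#' per host group is the number of positive samples divided by the samples in
#' the group, in percent; an `overall` row aggregates the cohort.
#'
#' @param calls `data.frame` of presence calls (rows from [call_presence()]).
#' @param manifest `data.frame` with columns `sample_id` and `host` covering
#'   every sample in the cohort (including samples with no calls, which count
#'   as negative).
#' @return `data.frame` with `host`, `positive_count`, `total_count`,
#'   `prevalence` (percent).
#' @export
prevalence <- function(calls, manifest) {
  stopifnot(all(c("sample_id", "host") %in% names(manifest)),
            !anyDuplicated(manifest$sample_id))
  if (!all(calls$sample_id %in% manifest$sample_id)) {
    stop("calls contain sample(s) absent from the manifest")
  }
  pos_samples <- unique(calls$sample_id[calls$present])
  manifest$positive <- manifest$sample_id %in% pos_samples
  agg <- lapply(split(manifest, manifest$host), function(m) {
    data.frame(host = m$host[1], positive_count = sum(m$positive),
               total_count = nrow(m),
               prevalence = 100 * sum(m$positive) / nrow(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- rbind(out, data.frame(
    host = "overall", positive_count = sum(manifest$positive),
    total_count = nrow(manifest),
    prevalence = 100 * sum(manifest$positive) / nrow(manifest),
    stringsAsFactors = FALSE
  ))
  rownames(out) <- NULL
  out
}

#' Subsample reads without replacement
#'
#' Deterministic given the seed; when fewer than `n` reads are supplied, all
#' are retained (in input order). Used to normalize samples to a common
#' sequencing depth before mapping.
#'
#' @param reads Vector of reads (or read identifiers).
#' @param n Target number of reads (default 1e7).
#' @param seed Integer seed.
#' @return Subsampled vector, in original relative order.
#' @export
subsample_reads <- function(reads, n = 1e7, seed = 1L) {
  stopifnot(n >= 0)
  if (length(reads) <= n) return(reads)
  idx <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    sort(sample.int(length(reads), n))
  })
  reads[idx]
}

#' Subsample a FASTQ file to a fixed read count
#'
#' @param infile Input FASTQ path (uncompressed or gzipped).
#' @param outfile Output FASTQ path.
#' @param n Target read count.
#' @param seed Integer seed.
#' @return Number of reads written, invisibly.
#' @export
subsample_fastq <- function(infile, outfile, n = 1e7, seed = 1L) {
  rec <- Biostrings::readQualityScaledDNAStringSet(infile)
  keep <- subsample_reads(seq_along(rec), n = n, seed = seed)
  Biostrings::writeQualityScaledXStringSet(rec[keep], outfile)
  invisible(length(keep))
}
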