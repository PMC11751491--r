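#' Voting-based containment search over a reference collection
#'
#' Classifies each read by the location-voting pipeline with sequence
#' alignment disabled: a read counts as mapped to the reference of its
#' top-voted cluster if that cluster reaches the vote threshold `V`, or
#' unconditionally to its rescue cluster when `recovery` is on (recovery
#' forces every read with at least one seed hit to map, which inflates
#' abundance estimates and is therefore off for profiling). Ties between
#' references with equal top votes resolve to the smallest reference id.
#'
#' @param reads read set (named character vector or `name`/`seq` data.frame).
#' @param idx a [build_index()] over the reference collection
#'   (`keep_sequences = FALSE` is fine).
#' @param D,V voting distance and vote threshold.
#' @param t minimizer cap for pattern alignment.
#' @param recovery force-map reads whose best cluster is below `V`.
#' @return a `containment_report` data.frame with one row per reference:
#'   `ref_id`, `ref_name`, `reads` (mapped-read count), `bases` (mapped-base
#'   sum), `coverage` (mapped bases / reference length); attribute
#'   `total_reads` holds the input read count.
#' @export
classify_read_set <- function(reads, idx, D = 100, V = 3L, t = 10L,
                              recovery = FALSE) {
  stopifnot(inherits(idx, "seed_index"))
  reads <- as_read_table(reads)
  if (nrow(reads) == 0L) stop("empty read set")
  P <- parse_pattern(idx$params$pattern)
  cfg <- pattern_align_config(t = t)
  k <- idx$params$k; w <- idx$params$w

  n_ref <- length(idx$ref_names)
  counts <- integer(n_ref)
  bases <- numeric(n_ref)
  for (i in seq_len(nrow(reads))) {
    codes <- encode_bases_cpp(toupper(reads$seq[i]))
    L <- length(codes)
    a <- if (P$p == 1L) 0L else
      which.max(pattern_align_sums(codes, P, idx, cfg)) - 1L
    pos <- pattern_positions(P, a, L)
    mm <- extract_minimizers_cpp(codes[pos + 1L], pos, k, w)
    if (nrow(mm) == 0L) next
    hits <- adjust_and_sort_hits(mm, idx, L)
    if (nrow(hits) == 0L) next
    top <- rescue_location(cluster_hits(hits, D))
    if (is.null(top)) next
    if (top$votes >= V || recovery) {
      counts[top$ref] <- counts[top$ref] + 1L
      bases[top$ref] <- bases[top$ref] + L
    }
  }
  structure(
    data.frame(ref_id = seq_len(n_ref), ref_name = idx$ref_names,
               reads = counts, bases = bases,
               coverage = ifelse(idx$lengths > 0, bases / idx$lengths, 0),
               stringsAsFactors = FALSE),
    class = c("containment_report", "data.frame"),
    total_reads = nrow(reads))
}

#' Accept references passing containment thresholds
#'
#' A reference is accepted when it attracted at least `min_reads` mapped
#' reads AND its coverage (mapped bases / reference length) is at least
#' `min_coverage`. Defaults are scaled for desk-size experiments; large-scale
#' screens would use values like 100000 reads and coverage 1.
#'
#' @param report a [classify_read_set()] report.
#' @param min_reads minimum mapped-read count.
#' @param min_coverage minimum coverage estimate.
#' @return character vector of accepted reference names.
#' @export
accept_targets <- function(report, min_reads = 50L, min_coverage = 0.05) {
  report$ref_name[report$reads >= min_reads & report$coverage >= min_coverage]
}

#' Proportional relative abundances over accepted references
#'
#' abundance_i = mapped_reads_i / sum of mapped reads over the accepted set.
#'
#' @param report a [classify_read_set()] report.
#' @param accepted character vector from [accept_targets()].
#' @return named numeric vector summing to 1.
#' @export
relative_abundance <- function(report, accepted) {
  sel <- report[report$ref_name %in% accepted, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no accepted references")
  tot <- sum(sel$reads)
  if (tot == 0) stop("accepted references have no mapped reads")
  setNames(sel$reads / tot, sel$ref_name)
}

#' Profile accuracy metrics: presence/absence F1 and abundance L1 error
#'
#' F1 is the harmonic mean of precision and recall over taxa presence
#' (abundance > 0); the L1 error is the sum of absolute differences between
#' true and predicted relative abundances over the union of taxa (a taxon
#' absent from one profile contributes its full abundance).
#'
#' @param predicted,truth named abundance vectors.
#' @return list with `f1`, `precision`, `recall`, `l1`.
#' @export
profile_metrics <- function(predicted, truth) {
  pred_taxa <- names(predicted)[predicted > 0]
  true_taxa <- names(truth)[truth > 0]
  tp <- length(intersect(pred_taxa, true_taxa))
  precision <- if (length(pred_taxa) > 0) tp / length(pred_taxa) else 0
  recall <- if (length(true_taxa) > 0) tp / length(true_taxa) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  taxa <- union(names(predicted), names(truth))
  p <- setNames(rep(0, length(taxa)), taxa); p[names(predicted)] <- predicted
  q <- setNames(rep(0, length(taxa)), taxa); q[names(truth)] <- truth
  list(f1 = f1, precision = precision, recall = recall,
       l1 = sum(abs(p - q)))
}

#' Write a containment report as TSV
#'
#' Columns: ref_id, reads, coverage, accepted, abundance (0 for
#' non-accepted references).
#'
#' @param report a [classify_read_set()] report.
#' @param accepted accepted reference names ([accept_targets()]).
#' @param file output path or connection.
#' @return invisibly, the table written.
#' @export
write_containment_tsv <- function(report, accepted, file = "") {
  ab <- rep(0, nrow(report))
  if (length(accepted) > 0) {
    abun <- relative_abundance(report, accepted)
    ab[match(names(abun), report$ref_name)] <- abun
  }
  out <- data.frame(ref_id = report$ref_name, reads = report$reads,
                    coverage = signif(report$coverage, 6),
                    accepted = report$ref_name %in% accepted,
                    abundance = signif(ab, 6))
  utils::write.table(out, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
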