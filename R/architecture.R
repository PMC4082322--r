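#' Read a domain-hit annotation table (TSV)
#'
#' The table must carry a header; column names can be remapped via
#' \code{columnMap} so externally produced annotation tables with different
#' headers can be ingested.
#'
#' @param path path to a TSV file.
#' @param columnMap named character vector mapping the canonical names
#'   \code{protein_id}, \code{domain}, \code{start}, \code{end}, \code{score}
#'   to the file's column names.
#' @return \code{data.frame} with the canonical columns.
#' @export
readHitsTable <- function(path,
                          columnMap = c(protein_id = "protein_id",
                                        domain = "domain", start = "start",
                                        end = "end", score = "score")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columnMap), names(df))
  if (length(missing))
    stop(sprintf("missing column(s) in hits table: %s",
                 paste(missing, collapse = ", ")))
  out <- data.frame(protein_id = as.character(df[[columnMap[["protein_id"]]]]),
                    domain = as.character(df[[columnMap[["domain"]]]]),
                    start = as.integer(df[[columnMap[["start"]]]]),
                    end = as.integer(df[[columnMap[["end"]]]]),
                    score = as.numeric(df[[columnMap[["score"]]]]))
  if (any(out$start < 1L | out$end < out$start))
    stop("malformed coordinates in hits table")
  out
}

#' Resolve overlapping domain hits on each protein
#'
#' Greedy selection by descending score (ties: earlier start, then domain
#' name): a candidate overlapping an already kept hit by more than
#' \code{max(10 residues, 20\% of the shorter hit)} is dropped; smaller
#' tolerated overlaps are trimmed from the lower-scoring hit so the result
#' is strictly non-overlapping and sorted by start.
#'
#' @param hits \code{data.frame} with columns \code{protein_id},
#'   \code{domain}, \code{start}, \code{end}, \code{score} (a single-protein
#'   table may omit \code{protein_id}).
#' @return The resolved hits, sorted by \code{protein_id} then \code{start}.
#' @export
resolveOverlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  if (is.null(hits$protein_id)) hits$protein_id <- "protein"
  if (any(hits$start < 1L | hits$end < hits$start))
    stop("malformed coordinates")
  out <- do.call(rbind, lapply(split(hits, hits$protein_id), .resolveOne))
  rownames(out) <- NULL
  out[order(out$protein_id, out$start), , drop = FALSE]
}

.resolveOne <- function(h) {
  h <- h[order(-h$score, h$start, h$domain), , drop = FALSE]
  kept <- h[0L, , drop = FALSE]
  for (r in seq_len(nrow(h))) {
    cand <- h[r, , drop = FALSE]
    ok <- TRUE
    for (k in seq_len(nrow(kept))) {
      ov <- min(cand$end, kept$end[k]) - max(cand$start, kept$start[k]) + 1L
      if (ov <= 0L) next
      shorter <- min(cand$end - cand$start + 1L, kept$end[k] - kept$start[k] + 1L)
      if (ov > max(10L, 0.2 * shorter)) { ok <- FALSE; break }
      # tolerated small overlap: trim the candidate away from the kept hit
      if (cand$start >= kept$start[k]) cand$start <- kept$end[k] + 1L
      else cand$end <- kept$start[k] - 1L
      if (cand$end < cand$start) { ok <- FALSE; break }
    }
    if (ok) kept <- rbind(kept, cand)
  }
  kept[order(kept$start), , drop = FALSE]
}

#' N-to-C architecture string of one protein's resolved hits
#'
#' @param hits resolved hits of a single protein (see [resolveOverlaps()]).
#' @return Domain names joined with \code{-} in N-to-C order; an empty hit
#'   list yields \code{""} with a warning.
#' @examples
#' architectureString(data.frame(domain = c("GRAM", "VASt"),
#'                               start = c(10, 120), end = c(80, 310),
#'                               score = c(50, 80)))
#' @export
architectureString <- function(hits) {
  if (!nrow(hits)) {
    warning("empty hit list; returning empty architecture")
    return("")
  }
  paste(hits$domain[order(hits$start)], collapse = "-")
}

#' Census statistics of domain architectures around a target domain
#'
#' Computes, over the proteins that contain the target domain: the
#' copy-number histogram of the target, the percentage with exactly one
#' copy, the percentage whose only identified domain is the target, the
#' co-occurrence percentage of every other domain, and counts of full
#' architecture strings. Percentages are exact internally; the print method
#' rounds to one decimal. Percentages computed over all proteins in the
#' table are also reported (\code{fractions_all_proteins}) for tables that
#' include target-free proteins.
#'
#' @param hits resolved hits \code{data.frame} (multiple proteins).
#' @param target target domain name (e.g. \code{"VASt"}).
#' @return An object of class \code{"ArchitectureSummary"}: a list with
#'   \code{n_proteins}, \code{copy_histogram}, \code{fraction_single_copy},
#'   \code{fraction_target_only}, \code{cooccurrence},
#'   \code{architecture_counts}, and \code{fractions_all_proteins}.
#' @export
architectureSummary <- function(hits, target) {
  hits <- resolveOverlaps(hits)
  byProt <- split(hits, hits$protein_id)
  copies <- vapply(byProt, function(h) sum(h$domain == target), integer(1))
  if (!any(copies > 0L)) stop(sprintf("target domain '%s' absent from all proteins", target))
  withTarget <- byProt[copies > 0L]
  cp <- copies[copies > 0L]
  nT <- length(withTarget)
  nAll <- length(byProt)
  hist <- table(factor(cp, levels = seq_len(max(cp))))
  othersPerProt <- lapply(withTarget, function(h) unique(setdiff(h$domain, target)))
  allOthers <- sort(unique(unlist(othersPerProt)))
  cooc <- vapply(allOthers, function(d)
    100 * mean(vapply(othersPerProt, function(o) d %in% o, logical(1))),
    numeric(1))
  archs <- vapply(withTarget, architectureString, character(1))
  out <- list(
    n_proteins = nT,
    n_proteins_total = nAll,
    copy_histogram = hist,
    fraction_single_copy = 100 * sum(cp == 1L) / nT,
    fraction_target_only = 100 * mean(lengths(othersPerProt) == 0L),
    cooccurrence = cooc,
    architecture_counts = sort(table(archs), decreasing = TRUE),
    fractions_all_proteins = list(
      fraction_single_copy = 100 * sum(cp == 1L) / nAll,
      fraction_target_only = 100 * sum(lengths(othersPerProt) == 0L) / nAll),
    target = target)
  class(out) <- "ArchitectureSummary"
  out
}

#' @export
print.ArchitectureSummary <- function(x, ...) {
  cat(sprintf("Architecture census for target '%s'\n", x$target))
  cat(sprintf("  %d proteins contain the target (of %d in table)\n",
              x$n_proteins, x$n_proteins_total))
  cat(sprintf("  single copy: %.1f%%   target-only: %.1f%%\n",
              x$fraction_single_copy, x$fraction_target_only))
  if (length(x$cooccurrence)) {
    cat("  co-occurring domains:\n")
    for (d in names(sort(x$cooccurrence, decreasing = TRUE)))
      cat(sprintf("    %-10s %.1f%%\n", d, x$cooccurrence[[d]]))
  }
  top <- utils::head(x$architecture_counts, 8L)
  cat("  top architectures:\n")
  for (a in names(top)) cat(sprintf("    %-30s %d\n", a, top[[a]]))
  invisible(x)
}

#' Write architecture counts as TSV and the summary as JSON lines
#'
#' @param summary an \code{ArchitectureSummary}.
#' @param countsPath path of the architecture-counts TSV (or \code{NULL}).
#' @param jsonPath path of the JSON summary (or \code{NULL}).
#' @return Invisibly, the summary.
#' @export
writeArchitectureSummary <- function(summary, countsPath = NULL, jsonPath = NULL) {
  if (!is.null(countsPath)) {
    utils::write.table(
      data.frame(architecture = names(summary$architecture_counts),
                 count = as.integer(summary$architecture_counts)),
      countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(
      target = summary$target,
      n_proteins = summary$n_proteins,
      n_proteins_total = summary$n_proteins_total,
      copy_histogram = as.list(stats::setNames(as.integer(summary$copy_histogram),
                                               names(summary$copy_histogram))),
      fraction_single_copy = summary$fraction_single_copy,
      fraction_target_only = summary$fraction_target_only,
      cooccurrence = as.list(summary$cooccurrence),
      fractions_all_proteins = summary$fractions_all_proteins),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
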