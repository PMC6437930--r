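# Four-criterion refinement of checkpoint-interacting proteins and the
# expression-by-outcome quadrant summary. Database-agnostic: interactions
# and annotations come from caller-supplied TSV tables, so results do not
# depend on a live (and version-drifting) interaction database.

#' Read an interaction / annotation table
#'
#' Interactions: protein_a, protein_b, evidence (experimental/predicted),
#' tissues (separator-delimited tags), sources. Annotations: protein,
#' os_association (positive/negative/none), tumor_expression
#' (increased/decreased/unchanged).
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_interactions <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "evidence", "tissues")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_input("interaction table lacks column(s): %s",
               paste(missing, collapse = ", "))
  x
}

#' @rdname read_interactions
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "os_association", "tumor_expression")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_input("annotation table lacks column(s): %s",
               paste(missing, collapse = ", "))
  bad <- setdiff(unique(x$os_association), c("positive", "negative", "none"))
  if (length(bad))
    stop_input("unknown os_association value(s): %s",
               paste(bad, collapse = ", "))
  bad <- setdiff(unique(x$tumor_expression),
                 c("increased", "decreased", "unchanged"))
  if (length(bad))
    stop_input("unknown tumor_expression value(s): %s",
               paste(bad, collapse = ", "))
  x
}

split_tags <- function(x) strsplit(x %||% "", "[;,|] *")

#' Refine checkpoint-interacting proteins by four criteria
#'
#' A candidate is any protein sharing at least one edge with a checkpoint
#' in `icp_set` (checkpoints themselves included: checkpoint-checkpoint
#' edges count toward redundancy). The refined set keeps proteins that
#' (1) have at least one experimentally validated checkpoint edge,
#' (2) interact with at least two distinct checkpoints, (3) carry an
#' overall-survival association annotation, and (4) have at least one
#' checkpoint edge supported in the required tissue. All four flags are
#' reported per candidate for audit.
#'
#' @param interactions interaction table (see [read_interactions()]);
#'   unordered duplicate pairs and self-edges are dropped
#' @param annotations annotation table; proteins absent from it fail
#'   criterion 3 with a warning
#' @param icp_set checkpoint protein names (non-empty)
#' @param tissue required tissue tag for criterion 4
#' @return data.frame, one row per candidate: protein, n_icp_partners,
#'   icp_partners, evidence_experimental, redundant, os_associated,
#'   tissue_supported, pass, os_association, tumor_expression
#' @export
refine_interactors <- function(interactions, annotations, icp_set,
                               tissue = "lung") {
  if (length(icp_set) == 0L) stop_input("icp_set must be non-empty")
  it <- interactions
  a <- pmin(it$protein_a, it$protein_b)
  b <- pmax(it$protein_a, it$protein_b)
  keep <- a != b & !duplicated(paste(a, b, it$evidence, it$tissues))
  it <- it[keep, , drop = FALSE]
  a <- a[keep]; b <- b[keep]

  icp_edge <- a %in% icp_set | b %in% icp_set
  it <- it[icp_edge, , drop = FALSE]
  a <- a[icp_edge]; b <- b[icp_edge]
  if (nrow(it) == 0L)
    return(data.frame(protein = character(0), n_icp_partners = integer(0),
                      icp_partners = character(0),
                      evidence_experimental = logical(0),
                      redundant = logical(0), os_associated = logical(0),
                      tissue_supported = logical(0), pass = logical(0),
                      os_association = character(0),
                      tumor_expression = character(0),
                      stringsAsFactors = FALSE))

  # per edge, the candidate(s) and the checkpoint partner(s); an edge
  # between two checkpoints contributes in both directions
  edges <- rbind(
    data.frame(protein = a, icp = b, evidence = it$evidence,
               tissues = it$tissues, stringsAsFactors = FALSE)[b %in% icp_set, ],
    data.frame(protein = b, icp = a, evidence = it$evidence,
               tissues = it$tissues, stringsAsFactors = FALSE)[a %in% icp_set, ])

  cand <- sort(unique(edges$protein))
  tags <- split_tags(edges$tissues)
  unannotated <- setdiff(cand, annotations$protein)
  if (length(unannotated))
    warning(sprintf("protein(s) without annotation treated as no OS association: %s",
                    paste(unannotated, collapse = ", ")))

  rows <- lapply(cand, function(p) {
    e <- edges$protein == p
    partners <- unique(edges$icp[e])
    ann <- annotations[match(p, annotations$protein), ]
    osa <- if (is.na(ann$protein)) "none" else ann$os_association
    data.frame(
      protein = p,
      n_icp_partners = length(partners),
      icp_partners = paste(sort(partners), collapse = ";"),
      evidence_experimental = any(edges$evidence[e] == "experimental"),
      redundant = length(partners) >= 2L,
      os_associated = osa != "none",
      tissue_supported = any(vapply(tags[e], function(tg) tissue %in% tg,
                                    logical(1))),
      os_association = osa,
      tumor_expression = if (is.na(ann$protein)) "unchanged" else
        ann$tumor_expression,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- out$evidence_experimental & out$redundant &
    out$os_associated & out$tissue_supported
  out <- out[, c("protein", "n_icp_partners", "icp_partners",
                 "evidence_experimental", "redundant", "os_associated",
                 "tissue_supported", "pass", "os_association",
                 "tumor_expression")]
  rownames(out) <- NULL
  out
}

#' Expression-by-outcome quadrant summary of refined interactors
#'
#' Contingency of tumor_expression (increased/decreased/unchanged) by
#' os_association (positive/negative/none) over the refined set, with
#' fractions, plus the per-checkpoint degree ranking (number of distinct
#' refined interactors), descending.
#'
#' @param refined output of [refine_interactors()]; rows with `pass ==
#'   FALSE` are ignored
#' @return list: `counts` (3 x 3 matrix), `fractions`, `n`, `icp_degree`
#'   data.frame (icp, degree)
#' @export
quadrant_summary <- function(refined) {
  r <- refined[refined$pass, , drop = FALSE]
  if (nrow(r) == 0L) stop_input("refined table is empty")
  counts <- table(
    factor(r$tumor_expression, c("increased", "decreased", "unchanged")),
    factor(r$os_association, c("positive", "negative", "none")))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("tumor_expression", "os_association")
  icps <- sort(unique(unlist(strsplit(r$icp_partners, ";"))))
  deg <- vapply(icps, function(i)
    sum(vapply(strsplit(r$icp_partners, ";"), function(ps) i %in% ps,
               logical(1))), integer(1))
  ord <- order(-deg, icps)
  list(counts = counts, fractions = counts / nrow(r), n = nrow(r),
       icp_degree = data.frame(icp = icps[ord], degree = unname(deg[ord]),
                               stringsAsFactors = FALSE))
}
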