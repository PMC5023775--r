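#' Discard ambiguous dual-species reads and count per gene
#'
#' Reads aligning to both the human and mouse transcriptomes cannot be
#' attributed to tumour or stroma and are discarded; the remaining reads
#' are counted to their assigned gene. Records whose assigned gene belongs
#' to the wrong species for their mapping flags are rejected and counted.
#'
#' @param aln Alignment summary data frame: `read_id`, `maps_human`,
#'   `maps_mouse`, `gene_id` (`NA` for unassigned).
#' @param gene_models A `gene_model_set` defining the species of every
#'   gene; when `NULL`, species is inferred from the mapping flags alone.
#' @return List: `counts` (named list with `human` and `mouse` named count
#'   vectors), `report` (fractions human/mouse/both/unassigned, summing to
#'   1), `n_discarded` (both-species reads), `n_rejected` (wrong-species
#'   gene assignments), `n_total`.
#' @export
disambiguate_reads <- function(aln, gene_models = NULL) {
  stopifnot(is.data.frame(aln), nrow(aln) > 0,
            all(c("read_id", "maps_human", "maps_mouse", "gene_id") %in%
                  names(aln)))
  n <- nrow(aln)
  both <- aln$maps_human & aln$maps_mouse
  h_only <- aln$maps_human & !aln$maps_mouse
  m_only <- aln$maps_mouse & !aln$maps_human
  unassigned <- !aln$maps_human & !aln$maps_mouse

  n_rejected <- 0L
  if (!is.null(gene_models)) {
    species <- gene_models$species[match(aln$gene_id, gene_models$gene_id)]
    bad <- (!both) & !is.na(aln$gene_id) &
      ((h_only & species != "human") | (m_only & species != "mouse"))
    bad[is.na(bad)] <- FALSE
    n_rejected <- sum(bad)
    if (n_rejected > 0) {
      warning(sprintf("%d reads assigned to a gene of the wrong species %s",
                      n_rejected, "were rejected"), call. = FALSE)
      h_only <- h_only & !bad
      m_only <- m_only & !bad
    }
  }
  count_species <- function(sel) {
    g <- aln$gene_id[sel & !is.na(aln$gene_id)]
    if (length(g) == 0) return(integer(0))
    tab <- table(g)
    stats::setNames(as.integer(tab), names(tab))
  }
  list(counts = list(human = count_species(h_only),
                     mouse = count_species(m_only)),
       report = c(human = sum(h_only), mouse = sum(m_only),
                  both = sum(both), unassigned = sum(unassigned) +
                    n_rejected) / n,
       n_discarded = sum(both), n_rejected = n_rejected, n_total = n)
}

#' Composite gene length
#'
#' The normalisation length of a gene is the total length of the union of
#' its exons ("non-overlapping exon groups"): overlapping or bookended
#' exons are merged before their widths are summed.
#'
#' @param exons Two-column matrix or data frame of half-open, 0-based
#'   exon intervals `[start, end)`.
#' @return Composite length in bp.
#' @examples
#' composite_gene_length(cbind(c(100, 150), c(200, 250)))  # 150
#' @export
composite_gene_length <- function(exons) {
  exons <- as.matrix(exons[, 1:2, drop = FALSE])
  if (nrow(exons) < 1) stop("gene without exons", call. = FALSE)
  if (any(exons[, 2] <= exons[, 1]))
    stop("invalid exon interval (end <= start)", call. = FALSE)
  r <- IRanges::IRanges(start = exons[, 1] + 1L, end = exons[, 2])
  sum(IRanges::width(IRanges::reduce(r, min.gapwidth = 1L)))
}

#' Composite lengths for every gene of a model set
#'
#' @param gene_models A `gene_model_set`.
#' @return Named integer vector of composite lengths, bp.
#' @export
gene_lengths <- function(gene_models) {
  sp <- split(gene_models[, c("start", "end")], gene_models$gene_id)
  vapply(sp, composite_gene_length, numeric(1))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = 1e9 * count / (total * length)` with the composite exon-group
#' length as the per-gene normalisation factor and the per-sample mapped
#' read total (of the same species) as denominator. Log2 values use a
#' configurable pseudo-offset: `log2(RPKM + offset)`.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Per-gene composite lengths, bp (recycled by gene name
#'   when named).
#' @param totals Per-sample mapped-read totals; defaults to the column
#'   sums of `counts`.
#' @param offset Pseudo-count added before the log2 transform.
#' @return List of class `expression_matrix`: `rpkm`, `log2`, `offset`.
#' @examples
#' compute_rpkm(matrix(10), lengths = 1000, totals = 1e6)$rpkm  # 10
#' @export
compute_rpkm <- function(counts, lengths, totals = colSums(counts),
                         offset = 1) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every gene needs a positive composite length", call. = FALSE)
  if (any(totals <= 0)) stop("per-sample totals must be positive",
                             call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  rpkm <- 1e9 * sweep(counts / lengths, 2, totals, "/")
  structure(list(rpkm = rpkm, log2 = log2(rpkm + offset), offset = offset),
            class = "expression_matrix")
}

#' Per-gene ANOVA differential expression against a control
#'
#' For every gene, a one-way ANOVA (via `aov()`) across treatment groups on
#' log2 RPKM values; per-contrast (treatment vs control) p-values come from
#' pooled-variance t statistics and are Bonferroni-corrected across the
#' contrast pairs. The log2 ratio is the difference of group means of log2
#' values. A gene-contrast is called significant when the corrected
#' p-value is below `alpha` and the absolute log2 ratio exceeds
#' `lfc_cutoff`.
#'
#' @param expr An `expression_matrix` (from [compute_rpkm()]) or a genes x
#'   samples matrix of log2 values.
#' @param treatments Treatment label per sample (column).
#' @param control Control label.
#' @param alpha Significance level on the corrected p-value.
#' @param lfc_cutoff Absolute log2-ratio cutoff.
#' @return Data frame: `gene`, `treatment`, `log2_ratio`, `omnibus_p`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
de_anova <- function(expr, treatments, control = "omalizumab",
                     alpha = 0.05, lfc_cutoff = 0.5) {
  L <- if (inherits(expr, "expression_matrix")) expr$log2 else as.matrix(expr)
  treatments <- factor(treatments)
  if (!control %in% levels(treatments))
    stop("control group missing", call. = FALSE)
  if (ncol(L) != length(treatments))
    stop("one treatment label per sample column is required", call. = FALSE)
  if (any(table(treatments) < 2))
    stop("every group needs >= 2 samples", call. = FALSE)
  trts <- setdiff(levels(treatments), control)
  k <- length(trts)
  genes <- rownames(L) %||% as.character(seq_len(nrow(L)))

  is_ctrl <- treatments == control
  out <- vector("list", nrow(L))
  for (i in seq_len(nrow(L))) {
    v <- L[i, ]
    if (stats::var(v) == 0) {
      out[[i]] <- data.frame(gene = genes[i], treatment = trts,
                             log2_ratio = 0, omnibus_p = 1, p_value = 1,
                             adjusted_p = 1)
      next
    }
    fit <- stats::aov(v ~ treatments)
    an <- summary(fit)[[1]]
    mse <- an[["Mean Sq"]][2]
    df_res <- an[["Df"]][2]
    m_ctrl <- mean(v[is_ctrl]); n_ctrl <- sum(is_ctrl)
    lr <- tstat <- numeric(k)
    for (j in seq_len(k)) {
      sel <- treatments == trts[j]
      lr[j] <- mean(v[sel]) - m_ctrl
      tstat[j] <- lr[j] / sqrt(mse * (1 / sum(sel) + 1 / n_ctrl))
    }
    p <- if (mse > 0) 2 * stats::pt(-abs(tstat), df_res) else
      as.numeric(lr == 0)
    out[[i]] <- data.frame(gene = genes[i], treatment = trts,
                           log2_ratio = lr, omnibus_p = an[["Pr(>F)"]][1],
                           p_value = p, adjusted_p = pmin(1, k * p))
  }
  res <- do.call(rbind, out)
  res$significant <- res$adjusted_p < alpha & abs(res$log2_ratio) > lfc_cutoff
  res
}

#' Partition significant gene sets by treatment exclusivity
#'
#' Exact set-algebra partition of the significant genes into blocks:
#' altered only by the bispecific antibody, shared exclusively with each
#' single-target antibody, altered by all three, and genes significant in
#' other treatments only.
#'
#' @param sets Named list of significant gene identifier vectors; must
#'   contain `vanucizumab`, and typically `LC06` and `bevacizumab`.
#' @return List of disjoint character vectors: `vanucizumab_only`,
#'   `vanucizumab_LC06_only`, `vanucizumab_bevacizumab_only`, `all_three`,
#'   `other`. Their union equals the union of the inputs.
#' @export
classify_de_sets <- function(sets) {
  if (!"vanucizumab" %in% names(sets))
    stop("'vanucizumab' set is required", call. = FALSE)
  V <- unique(sets$vanucizumab)
  L <- unique(sets$LC06 %||% character(0))
  B <- unique(sets$bevacizumab %||% character(0))
  list(vanucizumab_only = setdiff(V, union(L, B)),
       vanucizumab_LC06_only = setdiff(intersect(V, L), B),
       vanucizumab_bevacizumab_only = setdiff(intersect(V, B), L),
       all_three = intersect(V, intersect(L, B)),
       other = setdiff(union(L, B), V))
}

#' Read gene models from a GTF file
#'
#' Imports exon records and converts them to the package's 0-based
#' half-open `gene_model_set` layout.
#'
#' @param path GTF file.
#' @param species Species label attached to every gene.
#' @return A `gene_model_set` data frame.
#' @export
read_gene_models_gtf <- function(path, species = "human") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the 'rtracklayer' package", call. = FALSE)
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  gr <- gr[gr$type == "exon", ]
  gm <- data.frame(gene_id = gr$gene_id, species = species,
                   start = gr$start - 1L, end = gr$end,
                   strand = as.character(gr$strand))
  class(gm) <- c("gene_model_set", "data.frame")
  gm
}
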