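#' Simulation design for dual-species xenograft RNA-seq
#'
#' Describes a simulated xenograft sequencing experiment: reads come from
#' the human tumour compartment, the mouse stroma, an ambiguous fraction
#' mapping to both transcriptomes, and an unmapped remainder. Per-gene
#' expression is negative-binomial (log-normal baseline weights with a
#' per-gene-and-sample gamma multiplier of variance `dispersion`), and
#' selected genes carry multiplicative treatment effects.
#'
#' @param n_genes Genes per species.
#' @param groups Named integer vector: samples per treatment group.
#' @param human_fraction Fraction of mapped, unambiguous reads that are
#'   human.
#' @param ambiguous_fraction Fraction of all reads mapping to both
#'   transcriptomes.
#' @param unmapped_fraction Fraction of all reads mapping to neither.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param library_size Reads per sample.
#' @param de_spec Data frame with columns `gene` (human gene index,
#'   1-based), `treatments` (comma-separated labels) and `log2_effect`; or
#'   `NULL`.
#' @param seed RNG seed.
#' @return Object of class `rna_sim_design`.
#' @export
rna_sim_design <- function(n_genes = 2000,
                           groups = c(vanucizumab = 5, bevacizumab = 5,
                                      LC06 = 5, omalizumab = 5),
                           human_fraction = 0.8, ambiguous_fraction = 0.07,
                           unmapped_fraction = 0.30, dispersion = 0.05,
                           library_size = 1e6, de_spec = NULL, seed = 1L) {
  stop_if_not_scalar(human_fraction, "human_fraction", 0, 1, TRUE)
  stop_if_not_scalar(ambiguous_fraction, "ambiguous_fraction", 0, 1)
  stop_if_not_scalar(unmapped_fraction, "unmapped_fraction", 0, 1)
  stop_if_not_scalar(dispersion, "dispersion", 0, strict_lower = TRUE)
  if (ambiguous_fraction + unmapped_fraction >= 1)
    stop("ambiguous + unmapped fractions must leave room for mapped reads",
         call. = FALSE)
  if (length(groups) == 0 || any(groups < 1) || is.null(names(groups)))
    stop("'groups' must be a named vector of positive sample counts",
         call. = FALSE)
  if (!is.null(de_spec)) {
    stopifnot(all(c("gene", "treatments", "log2_effect") %in% names(de_spec)))
    if (any(de_spec$gene < 1 | de_spec$gene > n_genes))
      stop("de_spec gene indices out of range", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 human_fraction = human_fraction,
                 ambiguous_fraction = ambiguous_fraction,
                 unmapped_fraction = unmapped_fraction,
                 dispersion = dispersion,
                 library_size = as.integer(library_size),
                 de_spec = de_spec, seed = as.integer(seed)),
            class = "rna_sim_design")
}

#' Simulate a synthetic gene model set
#'
#' Draws per-gene exon structures (random exon counts, lengths and gaps,
#' occasionally overlapping) for both species, in 0-based half-open
#' transcript-genome coordinates.
#'
#' @param n_human,n_mouse Genes per species.
#' @param max_exons Maximum exons per gene.
#' @param seed RNG seed.
#' @return A `gene_model_set` data frame: `gene_id`, `species`, `start`,
#'   `end`, `strand` (one row per exon).
#' @export
simulate_gene_models <- function(n_human = 2000, n_mouse = 500,
                                 max_exons = 8, seed = 1L) {
  with_seed(seed, {
    one_species <- function(n, prefix) {
      rows <- lapply(seq_len(n), function(i) {
        k <- sample.int(max_exons, 1)
        len <- sample(80:400, k, replace = TRUE)
        gap <- sample(c(-50, 0, 50, 200, 1000), k, replace = TRUE,
                      prob = c(0.1, 0.1, 0.2, 0.4, 0.2))
        start <- cumsum(c(sample.int(5000, 1), (len + pmax(gap, -len %/% 2))[-k]))
        data.frame(gene_id = sprintf("%s%05d", prefix, i),
                   species = if (prefix == "ENSG") "human" else "mouse",
                   start = start, end = start + len,
                   strand = sample(c("+", "-"), 1))
      })
      do.call(rbind, rows)
    }
    gm <- rbind(one_species(n_human, "ENSG"), one_species(n_mouse, "ENSMUSG"))
    class(gm) <- c("gene_model_set", "data.frame")
    gm
  })
}

#' Simulate dual-species alignment summaries and counts
#'
#' For each sample, reads are assigned to the four alignment categories
#' (human-only, mouse-only, both-species, unmapped) by a multinomial draw
#' whose total is exactly the library size; unambiguous reads are then
#' distributed over the genes of their species with probabilities
#' proportional to per-gene negative-binomial expression weights. The
#' returned count matrices are the generator's truth: they equal what a
#' perfect disambiguation of the read-level summaries recovers.
#'
#' @param design An [rna_sim_design()].
#' @param gene_models A `gene_model_set` (see [simulate_gene_models()]);
#'   human genes beyond `design$n_genes` are ignored.
#' @param read_level If `TRUE`, also return per-read alignment summaries
#'   (one data frame per sample); skip for large designs where only counts
#'   are needed.
#' @return List: `counts_human`, `counts_mouse` (genes x samples),
#'   `samples` (sample, treatment), `summaries` (list or `NULL`),
#'   `category_counts` (4 x samples: human/mouse/both/unmapped),
#'   `true_log2_effects` (genes x groups matrix of spiked effects).
#' @export
simulate_xenograft_counts <- function(design, gene_models,
                                      read_level = FALSE) {
  stopifnot(inherits(design, "rna_sim_design"))
  hg <- unique(gene_models$gene_id[gene_models$species == "human"])
  mg <- unique(gene_models$gene_id[gene_models$species == "mouse"])
  if (length(hg) < design$n_genes)
    stop("gene_models carries fewer human genes than design$n_genes",
         call. = FALSE)
  hg <- hg[seq_len(design$n_genes)]
  if (length(mg) == 0) stop("gene_models has no mouse genes", call. = FALSE)

  p_amb <- design$ambiguous_fraction
  p_un <- design$unmapped_fraction
  p_h <- design$human_fraction * (1 - p_amb - p_un)
  p_m <- (1 - design$human_fraction) * (1 - p_amb - p_un)

  treatments <- rep(names(design$groups), design$groups)
  n_s <- length(treatments)
  sample_ids <- sprintf("%s_%d", treatments, stats::ave(seq_len(n_s),
                        treatments, FUN = seq_along))

  with_seed(design$seed, {
    base_h <- stats::rlnorm(length(hg), meanlog = 0, sdlog = 1)
    base_m <- stats::rlnorm(length(mg), meanlog = 0, sdlog = 1)
    eff <- matrix(0, length(hg), length(design$groups),
                  dimnames = list(hg, names(design$groups)))
    if (!is.null(design$de_spec)) {
      for (i in seq_len(nrow(design$de_spec))) {
        trs <- trimws(strsplit(design$de_spec$treatments[i], ",")[[1]])
        eff[design$de_spec$gene[i], trs] <- design$de_spec$log2_effect[i]
      }
    }
    counts_h <- matrix(0L, length(hg), n_s, dimnames = list(hg, sample_ids))
    counts_m <- matrix(0L, length(mg), n_s, dimnames = list(mg, sample_ids))
    cat_counts <- matrix(0L, 4, n_s,
                         dimnames = list(c("human", "mouse", "both",
                                           "unmapped"), sample_ids))
    summaries <- if (read_level) vector("list", n_s) else NULL
    shape <- 1 / design$dispersion
    for (s in seq_len(n_s)) {
      nc <- as.integer(stats::rmultinom(1, design$library_size,
                                        c(p_h, p_m, p_amb,
                                          1 - p_h - p_m - p_amb)))
      cat_counts[, s] <- nc
      lam_h <- base_h * 2^eff[, treatments[s]] *
        stats::rgamma(length(hg), shape = shape, scale = 1 / shape)
      lam_m <- base_m * stats::rgamma(length(mg), shape = shape,
                                      scale = 1 / shape)
      counts_h[, s] <- as.integer(stats::rmultinom(1, nc[1],
                                                   lam_h / sum(lam_h)))
      counts_m[, s] <- as.integer(stats::rmultinom(1, nc[2],
                                                   lam_m / sum(lam_m)))
      if (read_level) {
        gene <- c(rep(hg, counts_h[, s]), rep(mg, counts_m[, s]),
                  rep(NA_character_, nc[3] + nc[4]))
        maps_h <- c(rep(TRUE, nc[1]), rep(FALSE, nc[2]), rep(TRUE, nc[3]),
                    rep(FALSE, nc[4]))
        maps_m <- c(rep(FALSE, nc[1]), rep(TRUE, nc[2]), rep(TRUE, nc[3]),
                    rep(FALSE, nc[4]))
        summaries[[s]] <- data.frame(
          read_id = sprintf("r%07d", seq_len(design$library_size)),
          maps_human = maps_h, maps_mouse = maps_m, gene_id = gene)
      }
    }
    if (read_level) names(summaries) <- sample_ids
    list(counts_human = counts_h, counts_mouse = counts_m,
         samples = data.frame(sample = sample_ids, treatment = treatments),
         summaries = summaries, category_counts = cat_counts,
         true_log2_effects = eff)
  })
}
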