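## Synthetic paired expression + TCR cohorts. The generator emulates the
## structure of multi-animal virus-specific CD4+ T cell experiments:
## several samples per condition, subtype programs with elevated marker
## means, negative-binomial UMI counts, a clone-size law placing roughly
## half of the clonal space in large (>20 cell) clones, mostly private
## repertoires, and an optional planted fraction of fate-biased clones.

.default_subtypes <- c("Th1_Effector", "Tfh_Effector", "Tcmp", "Th1_Memory",
                       "Tfh_Memory", "Tcm", "Treg", "IFNI_Tfh", "Eomes_hi")
.default_background <- c(0.24, 0.21, 0.17, 0.12, 0.10, 0.09,
                         0.03, 0.02, 0.02)

## canonical marker symbols for the default subtypes; the remainder of each
## program is filled with synthetic symbols
.canonical_markers <- list(
  Th1_Effector = c("Cxcr6", "Ly6c2"),
  Tfh_Effector = c("Cxcr5", "Izumo1r"),
  Tcmp = c("Ccr7", "Slamf6"),
  Th1_Memory = c("Il18r1", "Klrd1"),
  Tfh_Memory = c("Sostdc1", "Id3"),
  Tcm = c("Tcf7", "Il7r"),
  Treg = c("Foxp3", "Ikzf2"),
  IFNI_Tfh = c("Ifi27", "Bst2"),
  Eomes_hi = c("Eomes", "Gzmk")
)

.mito_genes <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Co3", "Atp6",
                               "Atp8", "Cytb", "Nd3", "Nd4", "Nd4l", "Nd5",
                               "Nd6"))
.ribo_genes <- c(paste0("Rps", 2:13), paste0("Rpl", 3:14))

## one codon list per amino acid (standard genetic code) for random
## back-translation of CDR3 amino-acid strings
.codons <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC")
)
.aa_alphabet <- names(.codons)

#' Construct a synthetic-cohort specification
#'
#' Defaults describe the structure of the emulated experiments: nine
#' transcriptional subtypes (six major, three minor), two to three
#' samples, ~2000 cells per sample, a clone-size mixture placing about
#' half of the clonal space in clones above 20 cells, and ~10% of
#' expanded clonotypes planted with a strong fate bias.
#'
#' @param nSamples number of samples (default 3).
#' @param cellsPerSample target cells per sample (default 2000).
#' @param subtypes ordered subtype labels (default nine CD4+ states).
#' @param background subtype background frequencies, summing to 1.
#' @param nGenes gene-universe size (default 2000; must exceed ~1400 for
#'   QC stress cells).
#' @param nMarkerGenes marker genes per subtype (default 20).
#' @param markerLogFC natural-log fold elevation of markers (default 1).
#' @param baselineMean mean UMI per non-marker gene (default 1.5).
#' @param dispersion negative-binomial overdispersion (default 0.3).
#' @param cloneSizeLaw list; default
#'   `list(type = "mixture", large_fraction = 0.5, large_min = 25,
#'   large_max = 60, small_mean = 2, small_max = 20)`. Alternatives:
#'   `list(type = "uniform", min, max)` and `list(type = "fixed", sizes)`.
#' @param biasedFraction fraction of expanded (>= 10 cell) clonotypes
#'   planted with bias (default 0.1).
#' @param plantedBias target bias statistic for planted clones
#'   (default 0.8).
#' @param sharedClones list of character vectors of sample names; each
#'   entry plants one clonotype (3-8 cells per sample) in all listed
#'   samples. All other clonotypes are sample-private.
#' @param qcViolationRate per-rule fraction for [generateQCStressCells()].
#' @param cyclingFraction fraction of cells given a cell-cycle program.
#' @param doubletRate fraction of cells emitted with a second alpha chain.
#' @param seed RNG seed (default 42).
#' @return a validated [CohortSpec-class] object.
#' @export
cohortSpec <- function(nSamples = 3, cellsPerSample = 2000,
                       subtypes = .default_subtypes,
                       background = .default_background,
                       nGenes = 2000, nMarkerGenes = 20, markerLogFC = 1,
                       baselineMean = 1.5, dispersion = 0.3,
                       cloneSizeLaw = list(type = "mixture",
                                           large_fraction = 0.5,
                                           large_min = 25, large_max = 60,
                                           small_mean = 2, small_max = 20),
                       biasedFraction = 0.1, plantedBias = 0.8,
                       sharedClones = list(), qcViolationRate = 0,
                       cyclingFraction = 0, doubletRate = 0, seed = 42) {
  if (is.null(names(background))) names(background) <- subtypes
  methods::new("CohortSpec",
    nSamples = as.integer(nSamples),
    cellsPerSample = as.integer(cellsPerSample),
    subtypes = as.character(subtypes),
    background = background[subtypes],
    nGenes = as.integer(nGenes), nMarkerGenes = as.integer(nMarkerGenes),
    markerLogFC = markerLogFC, baselineMean = baselineMean,
    dispersion = dispersion, cloneSizeLaw = cloneSizeLaw,
    biasedFraction = biasedFraction, plantedBias = plantedBias,
    sharedClones = sharedClones, qcViolationRate = qcViolationRate,
    cyclingFraction = cyclingFraction, doubletRate = doubletRate,
    seed = .checkSeed(seed))
}

## gene universe: markers per subtype, mito/ribo/cycling blocks,
## housekeeping fill; returns data.frame(gene, class, subtype, mult)
.geneUniverse <- function(spec) {
  markers <- lapply(spec@subtypes, function(st) {
    canon <- .canonical_markers[[st]]
    if (is.null(canon)) canon <- character(0)
    n_extra <- max(0L, spec@nMarkerGenes - length(canon))
    c(head(canon, spec@nMarkerGenes),
      if (n_extra) paste0(st, ".mk", seq_len(n_extra)))
  })
  names(markers) <- spec@subtypes
  cyc <- head(.cycling_genes, 12L)
  core <- data.frame(
    gene = c(unlist(markers, use.names = FALSE), .mito_genes, .ribo_genes, cyc),
    class = c(rep("marker", sum(lengths(markers))),
              rep("mito", length(.mito_genes)),
              rep("ribo", length(.ribo_genes)),
              rep("cycling", length(cyc))),
    subtype = c(rep(spec@subtypes, lengths(markers)),
                rep(NA_character_, length(.mito_genes) + length(.ribo_genes) +
                      length(cyc))),
    stringsAsFactors = FALSE
  )
  n_fill <- spec@nGenes - nrow(core)
  if (n_fill < 0) stop("nGenes too small for the marker/mito/ribo blocks")
  fill <- data.frame(gene = paste0("Gm", 10000L + seq_len(n_fill)),
                     class = "housekeeping", subtype = NA_character_,
                     stringsAsFactors = FALSE)
  g <- rbind(core, fill)
  ## mean multipliers: mito/ribo genes carry realistic shares of the
  ## library (~5% mito, ~15% ribo at defaults)
  g$mult <- 1
  g$mult[g$class == "mito"] <- 8
  g$mult[g$class == "ribo"] <- 13
  rownames(g) <- g$gene
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## draw clone sizes summing exactly to n under the given law
.drawCloneSizes <- function(n, law) {
  type <- law$type %||% "mixture"
  if (type == "fixed") return(as.integer(law$sizes))
  draw_until <- function(target, rdraw) {
    sizes <- integer(0)
    tot <- 0L
    while (tot < target) {
      s <- rdraw()
      s <- min(s, target - tot)
      if (s >= 1L) sizes <- c(sizes, s)
      tot <- tot + s
    }
    sizes
  }
  if (type == "uniform") {
    return(draw_until(n, function() sample(law$min:law$max, 1L)))
  }
  n_large <- round((law$large_fraction %||% 0.5) * n)
  large <- draw_until(n_large, function() sample(law$large_min:law$large_max, 1L))
  small <- draw_until(n - sum(large), function() {
    min(1L + stats::rgeom(1L, prob = 1 / (law$small_mean %||% 2)),
        law$small_max %||% 20L)
  })
  c(large, small)
}

## random CDR3 amino-acid string C...F, length 10-16, plus a random codon
## back-translation; uniqueness enforced against `registry` (an env)
.randomCDR3 <- function(registry) {
  repeat {
    len <- sample(10:16, 1L)
    aa <- paste0("C", paste(sample(.aa_alphabet, len - 2L, replace = TRUE),
                            collapse = ""), "F")
    if (is.null(registry[[aa]])) {
      registry[[aa]] <- TRUE
      nt <- paste(vapply(strsplit(aa, "")[[1L]],
                         function(a) {
                           cs <- .codons[[a]]
                           if (length(cs) == 1L) cs else sample(cs, 1L)
                         }, ""), collapse = "")
      return(list(aa = aa, nt = nt))
    }
  }
}

.randomBarcodes <- function(n) {
  bc <- vapply(seq_len(n), function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 14L, replace = TRUE),
                 collapse = ""), sprintf("%04d", i), "-1")
  }, "")
  bc
}

## subtype frequencies a planted clone must have so that its expected bias
## equals c: focal frequency f = q + c * (1 - q)
.focalFrequency <- function(c_target, q_focal) {
  f <- q_focal + c_target * (1 - q_focal)
  if (f > 1 + 1e-12) {
    stop("requested planted bias is infeasible (focal frequency ", f, " > 1)")
  }
  min(f, 1)
}

#' Generate a synthetic paired expression/TCR cohort
#'
#' Cells are drawn clone-first: clone sizes come from the spec's
#' clone-size law; each cell of an unbiased clone receives a subtype from
#' the background multinomial; each cell of a planted-bias clone receives
#' the clone's focal subtype with probability `f` solving
#' `c = (f - q)/(1 - q)` for the requested bias, and one of the remaining
#' subtypes (proportionally to background) otherwise. UMI counts are
#' negative-binomial with marker means elevated by `exp(markerLogFC)` in
#' the marker's subtype. CDR3 pairs are unique per clone and disjoint
#' across samples except for explicitly shared clones. Deterministic
#' given the spec's seed.
#'
#' @param spec a [CohortSpec-class].
#' @param expression if `FALSE`, skip count-matrix generation (clonotype
#'   and label structure only); useful when only the repertoire and bias
#'   machinery is exercised.
#' @return list with elements `counts` (named list of
#'   [SingleCellExperiment::SingleCellExperiment] per sample, or `NULL`),
#'   `chains` (named list of chain data.frames in the
#'   [readTCRContigs()] layout), and `truth` (list: `subtype_of_cell`,
#'   `clonotype_of_cell`, `sample_of_cell` - named by `sample:barcode` -
#'   plus `planted_biased_clones` and `planted_shared_clones`
#'   data.frames and the `gene_table`).
#' @export
generateCohort <- function(spec, expression = TRUE) {
  methods::validObject(spec)
  set.seed(spec@seed)
  samples <- paste0("S", seq_len(spec@nSamples))
  genes <- .geneUniverse(spec)
  q <- spec@background
  registry <- new.env(parent = emptyenv())

  ## shared clonotype keys, generated once
  shared <- list()
  if (length(spec@sharedClones)) {
    for (i in seq_along(spec@sharedClones)) {
      in_samples <- spec@sharedClones[[i]]
      if (!all(in_samples %in% samples)) {
        stop("sharedClones refers to unknown sample(s)")
      }
      shared[[i]] <- c(.randomCDR3(registry), b = .randomCDR3(registry),
                       list(samples = in_samples))
    }
  }

  counts_list <- list()
  chains_list <- list()
  subtype_of_cell <- character(0)
  clonotype_of_cell <- character(0)
  sample_of_cell <- character(0)
  biased_rows <- list()

  for (s in samples) {
    sizes <- .drawCloneSizes(spec@cellsPerSample, spec@cloneSizeLaw)
    keys <- lapply(seq_along(sizes), function(i) {
      a <- .randomCDR3(registry); b <- .randomCDR3(registry)
      list(aa = paste(a$aa, b$aa, sep = "_"),
           nt = paste(a$nt, b$nt, sep = "_"),
           a = a, b = b)
    })
    focal <- rep(NA_character_, length(sizes))

    ## shared clones planted in this sample
    for (sh in shared) {
      if (s %in% sh$samples) {
        sizes <- c(sizes, sample(3:8, 1L))
        keys <- c(keys, list(list(
          aa = paste(sh$aa, sh$b.aa, sep = "_"),
          nt = paste(sh$nt, sh$b.nt, sep = "_"),
          a = list(aa = sh$aa, nt = sh$nt),
          b = list(aa = sh$b.aa, nt = sh$b.nt))))
        focal <- c(focal, NA_character_)
      }
    }

    ## plant bias in a fraction of expanded clones
    expanded_idx <- which(sizes >= 10L)
    n_bias <- round(spec@biasedFraction * length(expanded_idx))
    if (n_bias > 0) {
      chosen <- sample(expanded_idx, n_bias)
      focal[chosen] <- sample(spec@subtypes, n_bias, replace = TRUE, prob = q)
    }

    ## per-cell subtype, clone-first
    cell_subtype <- character(sum(sizes))
    cell_clone <- character(sum(sizes))
    pos <- 0L
    for (i in seq_along(sizes)) {
      sz <- sizes[i]
      if (is.na(focal[i])) {
        st <- sample(spec@subtypes, sz, replace = TRUE, prob = q)
      } else {
        f <- .focalFrequency(spec@plantedBias, q[focal[i]])
        is_focal <- stats::runif(sz) < f
        others <- setdiff(spec@subtypes, focal[i])
        st <- ifelse(is_focal, focal[i],
                     sample(others, sz, replace = TRUE,
                            prob = q[others] / sum(q[others])))
        biased_rows[[length(biased_rows) + 1L]] <- data.frame(
          sample = s, key_aa = keys[[i]]$aa, key_nt = keys[[i]]$nt,
          focal_subtype = focal[i], target_bias = spec@plantedBias,
          size = sz, stringsAsFactors = FALSE)
      }
      cell_subtype[pos + seq_len(sz)] <- st
      cell_clone[pos + seq_len(sz)] <- keys[[i]]$nt
      pos <- pos + sz
    }
    n_cells <- length(cell_subtype)
    barcodes <- .randomBarcodes(n_cells)
    cell_ids <- paste(s, barcodes, sep = ":")

    ## TCR chain table (one alpha + one beta per cell; optional 2nd alpha)
    clone_of_cell_idx <- rep(seq_along(sizes), sizes)
    a_aa <- vapply(keys, function(k) k$a$aa, "")[clone_of_cell_idx]
    a_nt <- vapply(keys, function(k) k$a$nt, "")[clone_of_cell_idx]
    b_aa <- vapply(keys, function(k) k$b$aa, "")[clone_of_cell_idx]
    b_nt <- vapply(keys, function(k) k$b$nt, "")[clone_of_cell_idx]
    chains_s <- data.frame(
      barcode = rep(barcodes, 2L),
      locus = rep(c("alpha", "beta"), each = n_cells),
      cdr3_aa = c(a_aa, b_aa), cdr3_nt = c(a_nt, b_nt),
      productive = TRUE, umis = 2L + stats::rpois(2L * n_cells, 2),
      sample = s, stringsAsFactors = FALSE)
    is_doublet <- stats::runif(n_cells) < spec@doubletRate
    if (any(is_doublet)) {
      extras <- lapply(which(is_doublet), function(i) .randomCDR3(registry))
      chains_s <- rbind(chains_s, data.frame(
        barcode = barcodes[is_doublet], locus = "alpha",
        cdr3_aa = vapply(extras, `[[`, "", "aa"),
        cdr3_nt = vapply(extras, `[[`, "", "nt"),
        productive = TRUE, umis = 1L, sample = s, stringsAsFactors = FALSE))
    }
    chains_list[[s]] <- chains_s[order(chains_s$barcode, chains_s$locus), ]
    rownames(chains_list[[s]]) <- NULL

    ## counts
    if (expression) {
      is_cycling <- stats::runif(n_cells) < spec@cyclingFraction
      mu_base <- spec@baselineMean * genes$mult
      mat <- matrix(0L, nrow = nrow(genes), ncol = n_cells)
      for (st in unique(cell_subtype)) {
        for (cyc in unique(is_cycling[cell_subtype == st])) {
          cols <- which(cell_subtype == st & is_cycling == cyc)
          mu <- mu_base
          mk <- which(genes$class == "marker" & genes$subtype == st)
          mu[mk] <- mu[mk] * exp(spec@markerLogFC)
          if (cyc) {
            cg <- which(genes$class == "cycling")
            mu[cg] <- mu[cg] * exp(2)
          }
          mat[, cols] <- stats::rnbinom(nrow(genes) * length(cols),
                                        size = 1 / spec@dispersion, mu = mu)
        }
      }
      m <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
      rownames(m) <- genes$gene
      colnames(m) <- cell_ids
      counts_list[[s]] <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(sample = rep(s, n_cells),
                                       barcode = barcodes,
                                       cycling = is_cycling,
                                       row.names = cell_ids))
    }

    subtype_of_cell[cell_ids] <- cell_subtype
    clonotype_of_cell[cell_ids] <- cell_clone
    sample_of_cell[cell_ids] <- s
  }

  planted_shared <- if (length(shared)) {
    do.call(rbind, lapply(shared, function(sh) data.frame(
      key_aa = paste(sh$aa, sh$b.aa, sep = "_"),
      key_nt = paste(sh$nt, sh$b.nt, sep = "_"),
      samples = paste(sh$samples, collapse = ","),
      stringsAsFactors = FALSE)))
  } else {
    data.frame(key_aa = character(0), key_nt = character(0),
               samples = character(0))
  }
  planted_biased <- if (length(biased_rows)) {
    do.call(rbind, biased_rows)
  } else {
    data.frame(sample = character(0), key_aa = character(0),
               key_nt = character(0), focal_subtype = character(0),
               target_bias = numeric(0), size = integer(0))
  }

  list(
    counts = if (expression) counts_list else NULL,
    chains = chains_list,
    truth = list(
      subtype_of_cell = subtype_of_cell,
      clonotype_of_cell = clonotype_of_cell,
      sample_of_cell = sample_of_cell,
      planted_biased_clones = planted_biased,
      planted_shared_clones = planted_shared,
      gene_table = genes
    )
  )
}

#' Marker gene sets of a cohort's planted subtype programs
#'
#' Convenience accessor for the ground-truth marker signatures of a
#' generated cohort (used to drive signature-guided annotation in tests
#' and examples).
#'
#' @param cohort output of [generateCohort()].
#' @return named list of character vectors, one per subtype.
#' @export
cohortMarkerSets <- function(cohort) {
  g <- cohort$truth$gene_table
  mk <- g[g$class == "marker", ]
  split(mk$gene, mk$subtype)[unique(mk$subtype)]
}

#' Generate cells that each violate exactly one QC rule
#'
#' Emits labeled cells violating one rule each: too few detected genes
#' (< 700), too few or too many UMIs (outside (1500, 15000)), excessive
#' mitochondrial fraction (>= 10%) or excessive ribosomal fraction
#' (>= 50%), with mitochondrial genes named `mt-*` and ribosomal genes
#' `Rps*`/`Rpl*`. All other QC parameters of each cell are kept well
#' inside the compliant range. Requires a gene universe of at least
#' ~1400 genes.
#'
#' @param spec a [CohortSpec-class]; `qcViolationRate` times
#'   `cellsPerSample` cells are emitted per rule unless `nPerRule` is
#'   given.
#' @param nPerRule optional explicit number of cells per rule.
#' @return [SingleCellExperiment::SingleCellExperiment] with
#'   `colData$violation` naming the violated rule; zero columns when the
#'   requested number is zero.
#' @export
generateQCStressCells <- function(spec, nPerRule = NULL) {
  set.seed(spec@seed + 1L)
  if (is.null(nPerRule)) {
    nPerRule <- round(spec@qcViolationRate * spec@cellsPerSample)
  }
  genes <- .geneUniverse(spec)
  n_genes <- nrow(genes)
  other <- which(!genes$class %in% c("mito", "ribo"))
  mito <- which(genes$class == "mito")
  ribo <- which(genes$class == "ribo")
  if (length(other) < 1350L) {
    stop("gene universe too small for QC stress cells (need >= ~1400 genes)")
  }

  draw <- function(pool, n_umi, replace = TRUE) {
    tabulate(sample(pool, n_umi, replace = replace), nbins = n_genes)
  }
  rules <- list(
    low_genes = function() draw(sample(other, 400L), 3000L),
    low_umi   = function() draw(sample(other, 1000L), 1000L, replace = FALSE),
    high_umi  = function() draw(other, 20000L),
    high_mito = function() draw(mito, 450L) + draw(sample(other, 900L), 2550L),
    high_ribo = function() draw(ribo, 1800L) + draw(sample(other, 1300L), 1500L)
  )
  cols <- list(); labels <- character(0)
  for (rule in names(rules)) {
    for (i in seq_len(nPerRule)) {
      cols[[length(cols) + 1L]] <- rules[[rule]]()
      labels <- c(labels, rule)
    }
  }
  m <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(0L, nrow = n_genes, ncol = 0L)
  }
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  rownames(m) <- genes$gene
  barcodes <- if (length(labels)) {
    paste0(labels, ".", ave(seq_along(labels), labels, FUN = seq_along))
  } else {
    character(0)
  }
  colnames(m) <- if (length(barcodes)) {
    paste("qc_stress", barcodes, sep = ":")
  } else {
    character(0)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(sample = rep("qc_stress", length(labels)),
                                   barcode = barcodes, violation = labels,
                                   row.names = colnames(m)))
}

#' Combine a cohort's per-sample counts into one experiment
#'
#' Column-binds the per-sample count matrices of a generated cohort (or
#' any named list of SingleCellExperiments sharing genes) into a single
#' [SingleCellExperiment::SingleCellExperiment], preserving the `sample`
#' annotation.
#'
#' @param x output of [generateCohort()] or a named list of
#'   SingleCellExperiments with identical rownames.
#' @return a single SingleCellExperiment.
#' @export
combineSamples <- function(x) {
  sces <- if (is.list(x) && !is.null(x$counts)) x$counts else x
  mats <- lapply(sces, function(s) .getCounts(s))
  genes <- rownames(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(rownames(m), genes), TRUE))) {
    stop("all samples must share an identical gene universe")
  }
  m <- do.call(cbind, mats)
  cd <- do.call(rbind, lapply(sces, function(s) {
    as.data.frame(SummarizedExperiment::colData(s))
  }))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cd, row.names = colnames(m)))
}
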