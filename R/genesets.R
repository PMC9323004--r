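## Built-in mouse gene lists and prefixes used for variable-gene exclusion
## and signature hygiene. All user-overridable at the call sites.

# Cell-cycle program (core S and G2/M markers, mouse symbols). Cycling cells
# cluster by phase rather than lineage if these genes enter the panel, so
# they are excluded from variable-gene selection by default.
.cycling_genes <- c(
  "Mki67", "Top2a", "Ccnb1", "Ccnb2", "Ccna2", "Ccne1", "Cdk1", "Cdc20",
  "Birc5", "Bub1", "Bub1b", "Plk1", "Aurka", "Aurkb", "Mcm2", "Mcm3",
  "Mcm4", "Mcm5", "Mcm6", "Mcm7", "Pcna", "Rrm1", "Rrm2", "Tyms", "Ung",
  "Uhrf1", "Hells", "Tipin", "Gins2", "Cenpa", "Cenpe", "Cenpf", "Tpx2",
  "Ube2c", "Hmgb2", "Stmn1", "Tubb5", "H2afz"
)

# Sex-specific transcripts removed from differential signatures.
.sex_genes <- c("Xist", "Tsix", "Ddx3y", "Eif2s3y", "Uty", "Kdm5d")

# Symbol prefixes, mouse convention.
.mito_prefix <- "mt-"
.ribo_prefixes <- c("Rps", "Rpl")
.hsp_prefixes <- "Hsp"
.isg_prefixes <- c("Ifit", "Isg", "Irf7", "Oas", "Mx1", "Mx2", "Rsad2")
.tcr_prefixes <- c("Trav", "Traj", "Trac", "Trbv", "Trbd", "Trbj", "Trbc",
                   "Trgv", "Trgj", "Trgc", "Trdv", "Trdj", "Trdc")

.matchPrefixes <- function(genes, prefixes) {
  if (length(prefixes) == 0L) return(character(0))
  hit <- Reduce(`|`, lapply(prefixes, function(p) startsWith(genes, p)))
  genes[hit]
}

#' Built-in exclusion gene sets
#'
#' Returns the genes among `genes` that belong to each built-in class:
#' mitochondrial (`mt-`), ribosomal (`Rps`/`Rpl`), heat-shock (`Hsp`),
#' interferon-stimulated, cell-cycle, TCR segment genes and sex-specific
#' transcripts. These are the default exclusion lists for variable-gene
#' selection and for cleaning differential signatures.
#'
#' @param genes character vector of gene symbols (mouse convention).
#' @return named list of character vectors (subsets of `genes`).
#' @export
builtinGeneSets <- function(genes) {
  list(
    mito      = .matchPrefixes(genes, .mito_prefix),
    ribo      = .matchPrefixes(genes, .ribo_prefixes),
    heatshock = .matchPrefixes(genes, .hsp_prefixes),
    isg       = .matchPrefixes(genes, .isg_prefixes),
    cycling   = intersect(genes, .cycling_genes),
    tcr       = .matchPrefixes(genes, .tcr_prefixes),
    sex       = intersect(genes, .sex_genes)
  )
}
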