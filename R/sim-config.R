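#' Default marker specification for the simulated populations
#'
#' Five glial progenitor (OPC) subpopulations plus an induced-neuron
#' population, each defined by a named vector of marker genes and their
#' fold-elevation over baseline. The glial sets follow the field's standard
#' markers: early progenitors (VCAN, NFIA), OPC-committed cells (OLIG1/2,
#' SOX10), cycling cells (TOP2A, MKI67), bipotent/astrocyte-leaning cells
#' (GFAP, SLC1A3, CD44) and early astrocytes (AQP4, SPARCL1); the neuronal
#' set carries dopaminergic and pan-neuronal maturation markers (TH, RET,
#' KCNJ6, SLC6A3, NR4A2, SYT1, MAPT, ...). The neuron set is disjoint from
#' every glial set.
#'
#' @return Named list mapping population name to a named numeric vector
#'   (gene -> fold-elevation).
#' @export
default_marker_spec <- function() {
  list(
    OPC1 = c(VCAN = 8, NFIA = 6, HES1 = 6, FABP7 = 6, TNC = 8, LGALS3 = 6,
             SERPINE2 = 6, MEST = 4, ID3 = 4, EDNRB = 6, TTYH1 = 4, PEA15 = 4),
    OPC2 = c(OLIG1 = 8, OLIG2 = 6, SOX10 = 6, CSPG4 = 8, GPR17 = 8, LHFPL3 = 6,
             DLL3 = 6, SHD = 4, BCAN = 6, NKX2_2 = 6, CNTN1 = 4, SIRT2 = 4),
    OPC3 = c(TOP2A = 10, MKI67 = 10, CENPF = 8, UBE2C = 8, BIRC5 = 8, CCNB1 = 6,
             NUSAP1 = 6, PBK = 6, TPX2 = 6, ASPM = 4, RRM2 = 4, CDK1 = 6),
    OPC4 = c(GFAP = 8, SLC1A3 = 6, CD44 = 8, S100A10 = 6, VIM = 4, TIMP1 = 6,
             CRYAB = 6, ANXA2 = 6, TAGLN = 4, ITGA7 = 4, LGALS1 = 4, TPM1 = 4),
    OPC5 = c(AQP4 = 10, SPARCL1 = 8, SOX9 = 4, CLU = 8, MT2A = 6, AGT = 8,
             GJA1 = 6, FGFR3 = 6, MLC1 = 6, ATP1B2 = 4, HEPN1 = 6, PON2 = 4),
    neuron = c(TH = 10, RET = 8, KCNJ6 = 8, SLC6A3 = 8, NR4A2 = 8, SYT1 = 6,
               MAPT = 6, SLC18A2 = 6, KCNN3 = 4, CACNA2D1 = 4, DRD2 = 4,
               GFRA1 = 4, SNAP25 = 8, STMN2 = 8, GAP43 = 6, NEFL = 6,
               DCX = 6, SYN3 = 6, NFASC = 4, INA = 6)
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulator with validation. Defaults encode
#' the study conditions the downstream analysis assumes: five OPC clusters
#' with fixed starting proportions, a neuronal population growing from 21%
#' of cells one day after induction to 76% at day 21, negative-binomial UMI
#' counts, Poisson transgene copy numbers at a multiplicity of infection of
#' 1-2 per vector, a 20-nt lineage barcode flanked by `GTCGTGA`/`CTCGAC`
#' with a static 12-nt library ID, a barcode library diversity of about one
#' million, and barcode reads captured from about 60% of cells.
#'
#' @param n_cells_per_timepoint Cells simulated at each timepoint.
#' @param timepoints Ordered character vector of timepoint labels.
#' @param cluster_proportions Named fractions of the five glial clusters at
#'   the first timepoint; must sum to 1.
#' @param neuron_fraction_by_timepoint Named per-timepoint neuron fractions
#'   in `[0, 1]`.
#' @param n_genes Number of endogenous genes (markers included).
#' @param n_mito Number of mitochondrial (`MT-`) features.
#' @param marker_spec Marker specification, see [default_marker_spec()].
#' @param mean_umi_per_cell Expected library size per cell.
#' @param umi_sdlog Log-normal spread of library sizes.
#' @param abundance_sdlog Log-normal spread of gene baseline abundances.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param mito_share Expected fraction of counts on mitochondrial features.
#' @param moi Poisson mean of transgene vector copies per cell per factor.
#' @param transgene_capture_rate Probability a transgene molecule is
#'   observed as a UMI.
#' @param transgene_expr_per_copy Transgene molecules produced per
#'   integrated copy.
#' @param transgene_names Feature names of the three conversion factors.
#' @param n_barcodes_library Barcode library diversity.
#' @param barcode_len Lineage barcode length; fixed at 20 nt.
#' @param flank5,flank3 Static flanks around the barcode in R2.
#' @param library_id Static 12-nt library identifier placed 3' of `flank3`.
#' @param seq_error_rate Per-base substitution rate on R2.
#' @param decoy_fraction Fraction of emitted reads lacking the motif.
#' @param barcode_capture_rate Probability a cell yields barcode reads.
#' @param mean_barcode_umis Mean distinct barcode UMIs per captured cell.
#' @param read_len_r2 R2 read length.
#' @param n_clones Number of multi-cell clones planted.
#' @param clone_geom_p Geometric parameter of post-window clone sizes
#'   (long-tailed; a handful of large clones).
#' @param clone_size_max Truncation of the clone-size distribution.
#' @param post_timepoints Timepoints forming the post-induction window used
#'   for clonal conversion.
#' @param conversion_base_rate Baseline probability that a clone's
#'   post-window cell is a neuron.
#' @param cluster_conversion_effect Named multiplier per origin cluster;
#'   all 1 gives the exchangeable null.
#' @param seed Integer seed; all stage randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_timepoint = 500,
                       timepoints = c("D0", "D2", "D3", "D5", "D7", "D14", "D21"),
                       cluster_proportions = c(OPC1 = 0.30, OPC2 = 0.20, OPC3 = 0.24,
                                               OPC4 = 0.10, OPC5 = 0.16),
                       neuron_fraction_by_timepoint = c(D0 = 0, D2 = 0.21, D3 = 0.30,
                                                        D5 = 0.40, D7 = 0.50, D14 = 0.65,
                                                        D21 = 0.76),
                       n_genes = 2000,
                       n_mito = 10,
                       marker_spec = default_marker_spec(),
                       mean_umi_per_cell = 4634,
                       umi_sdlog = 0.25,
                       abundance_sdlog = 1.0,
                       dispersion = 2,
                       mito_share = 0.004,
                       moi = 1.5,
                       transgene_capture_rate = 0.5,
                       transgene_expr_per_copy = 20,
                       transgene_names = c("tg-ASCL1", "tg-LMX1A", "tg-NURR1"),
                       n_barcodes_library = 1e6,
                       barcode_len = 20,
                       flank5 = "GTCGTGA",
                       flank3 = "CTCGAC",
                       library_id = "ACGGTCTAGCAT",
                       seq_error_rate = 0.001,
                       decoy_fraction = 0.4,
                       barcode_capture_rate = 0.6,
                       mean_barcode_umis = 2.5,
                       read_len_r2 = 98,
                       n_clones = 66,
                       clone_geom_p = 0.2,
                       clone_size_max = 30,
                       post_timepoints = intersect(c("D2", "D3", "D5", "D7"), timepoints),
                       conversion_base_rate = 0.5,
                       cluster_conversion_effect = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$cluster_conversion_effect)) {
    cfg$cluster_conversion_effect <-
      stats::setNames(rep(1, length(cfg$cluster_proportions)), names(cfg$cluster_proportions))
  }
  with(cfg, {
    if (n_cells_per_timepoint < 1) stop_ct("n_cells_per_timepoint must be positive")
    if (abs(sum(cluster_proportions) - 1) > 1e-9)
      stop_ct("cluster_proportions must sum to 1 (got ", sum(cluster_proportions), ")")
    if (is.null(names(cluster_proportions)) || any(cluster_proportions < 0))
      stop_ct("cluster_proportions must be a named non-negative vector")
    probs <- c(neuron_fraction_by_timepoint, transgene_capture_rate,
               seq_error_rate, decoy_fraction, barcode_capture_rate,
               conversion_base_rate, mito_share)
    if (any(probs < 0 | probs > 1)) stop_ct("all probabilities must lie in [0, 1]")
    if (!all(timepoints %in% names(neuron_fraction_by_timepoint)))
      stop_ct("neuron_fraction_by_timepoint must name every timepoint")
    if (barcode_len != 20L) stop_ct("barcode_len is fixed at 20")
    if (nchar(library_id) != 12L) stop_ct("library_id must be 12 nt")
    if (!all(post_timepoints %in% timepoints))
      stop_ct("post_timepoints must be a subset of timepoints")
    if (dispersion <= 0 || mean_umi_per_cell <= 0 || moi < 0)
      stop_ct("dispersion and mean_umi_per_cell must be positive, moi non-negative")
    if (!all(names(cluster_conversion_effect) %in% names(cluster_proportions)) ||
        any(cluster_conversion_effect < 0))
      stop_ct("cluster_conversion_effect must be non-negative and named by cluster")
  })
  structure(cfg, class = "sim_config")
}
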