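#' Bundled synthetic example data
#'
#' Three keyed collections for trial use, regenerated deterministically in
#' code on first access: `dna_pfms` (transcription-factor-like DNA motif
#' count matrices), `dna_seqs` (aligned DNA sequence sets) and `aa_seqs`
#' (kinase-substrate-like amino-acid windows centered on a phosphosite).
#' All of it is **synthetic** — simulated with [simulate_sequences()]
#' around documented consensus motifs at fixed seeds — and only emulates
#' the shape of real motif databases; no external data is redistributed.
#' Labels carry a `SYN` prefix to make the synthetic provenance explicit.
#'
#' @return A list with elements `dna_pfms` (named list of
#'   [freq_matrix()]), `dna_seqs` and `aa_seqs` (named lists of
#'   [seq_set()]).
#' @examples
#' names(example_data())
#' names(example_data()$dna_pfms)
#' @export
example_data <- function() {
  if (!is.null(.seqgrammar_cache$example_data)) {
    return(.seqgrammar_cache$example_data)
  }
  # DNA: AP-1-like TGACTCA, E-box-like CACGTGAC, GC-box-like GGGGCGGGG
  dna_spec <- list(
    SYN_TF_M0001 = list(cons = "TGACTCA",   seed = 101L),
    SYN_TF_M0002 = list(cons = "CACGTGAC",  seed = 102L),
    SYN_TF_M0003 = list(cons = "GGGGCGGGG", seed = 103L)
  )
  dna_seqs <- lapply(names(dna_spec), function(nm) {
    s <- dna_spec[[nm]]
    simulate_sequences(s$cons, n = 50, mutation_rate = 0.15,
                       alphabet = alphabet_dna(), seed = s$seed,
                       panel_label = nm)
  })
  names(dna_seqs) <- names(dna_spec)
  dna_pfms <- lapply(dna_seqs, build_pfm)

  # AA: 15-mer windows with a central S/T phosphosite and basic or
  # proline-directed context, kinase-motif style
  aa_spec <- list(
    SYN_KIN_AKT  = list(cons = "AVRKRGRSFSGLMDE", seed = 201L),
    SYN_KIN_CDK  = list(cons = "GHKLARSSPEKRVLD", seed = 202L),
    SYN_KIN_CK2  = list(cons = "MGDLESSDDEVFARH", seed = 203L)
  )
  aa_seqs <- lapply(names(aa_spec), function(nm) {
    s <- aa_spec[[nm]]
    simulate_sequences(s$cons, n = 40, mutation_rate = 0.3,
                       alphabet = alphabet_aa(), seed = s$seed,
                       panel_label = nm)
  })
  names(aa_seqs) <- names(aa_spec)

  out <- list(dna_pfms = dna_pfms, dna_seqs = dna_seqs, aa_seqs = aa_seqs)
  .seqgrammar_cache$example_data <- out
  out
}
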