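#' Configuration for the synthetic compound-library generator
#'
#' The generator assembles drug-like molecules from a fixed fragment
#' grammar (scaffolds of one to three rings crossed with two substituent
#' sites: alkyl chains, halogens, basic amines, carboxylic acids, ...) and
#' attaches a positive continuous endpoint with a known generative model:
#'
#' \deqn{endpoint = \exp(\beta_1 z(lipo) + \beta_2 z(polar) +
#'       \gamma z(rings) + \epsilon), \quad \epsilon \sim N(0, noise\_sd)}
#'
#' where `lipo` and `polar` are fragment lipophilicity/polarity scores,
#' `rings` is the scaffold ring count, and `z()` is the within-library
#' z-score. When `image_signal_weight` (\eqn{\gamma}) is positive, the
#' ring-count term is the structural signal intended to be visible in
#' snapshot images but withheld from the descriptor table (see
#' [synthetic_withheld_descriptors()]), giving a controllable analog of an
#' image-derived feature that carries information beyond the descriptors.
#' The binary class label thresholds the endpoint at `threshold` (default
#' 1, the classification cut used for clearance in L/h/kg).
#'
#' @param n_compounds number of compounds (>= 20).
#' @param seed integer seed; the library is a pure function of the config.
#' @param noise_sd standard deviation of the log-scale noise (default 0.3).
#' @param image_signal_weight \eqn{\gamma}, weight of the ring-count term
#'   (default 1).
#' @param threshold class boundary on the endpoint scale (default 1).
#' @param beta length-2 numeric, weights of the lipophilicity and polarity
#'   terms (default `c(0.7, -0.5)`).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_compounds = 300L, seed = 1L, noise_sd = 0.3,
                         image_signal_weight = 1, threshold = 1,
                         beta = c(0.7, -0.5)) {
  stopifnot(n_compounds >= 20L, noise_sd >= 0, length(beta) == 2L)
  structure(list(n_compounds = as.integer(n_compounds), seed = as.integer(seed),
                 noise_sd = noise_sd, image_signal_weight = image_signal_weight,
                 threshold = threshold, beta = beta),
            class = "synth_config")
}

fragment_grammar <- function() sq_data("fragment_grammar.csv")

# Substitute the two sites of a scaffold template. The branch site {A} is
# wrapped in parentheses; the tail site {T} is appended bare.
assemble_smiles <- function(template, sub_a, sub_t) {
  a <- if (nzchar(sub_a)) paste0("(", sub_a, ")") else ""
  s <- sub("{A}", a, template, fixed = TRUE)
  sub("{T}", sub_t, s, fixed = TRUE)
}

#' Generate a reproducible synthetic compound library
#'
#' Draws `n_compounds` distinct scaffold/substituent combinations from the
#' fragment grammar (without replacement; exhausting the grammar is an
#' error) and attaches endpoints and class labels per the generative model
#' described in [synth_config()]. The generative terms (lipophilicity,
#' polarity, ring count, latent mean) are returned in the
#' `generative_terms` attribute so tests can check the noiseless limit.
#'
#' @param config a [synth_config()].
#' @return a `compound_library` of [compound_record()]s, deterministic in
#'   the config.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- fragment_grammar()
  sc <- g[g$kind == "scaffold", ]
  su <- g[g$kind == "substituent", ]
  su$smiles[is.na(su$smiles)] <- ""
  n_comb <- nrow(sc) * nrow(su) * nrow(su)
  if (config$n_compounds > n_comb)
    stop(sprintf(paste0("fragment grammar exhausted: %d distinct combinations ",
                        "available but %d compounds requested; extend the grammar"),
                 n_comb, config$n_compounds))
  sq_with_seed(derive_seed(config$seed, 11L), {
    pick <- sample.int(n_comb, config$n_compounds)
    eps <- stats::rnorm(config$n_compounds, 0, config$noise_sd)
  })
  # decode combination index -> (scaffold, substituent A, substituent T)
  i_sc <- ((pick - 1L) %% nrow(sc)) + 1L
  rest <- (pick - 1L) %/% nrow(sc)
  i_a <- (rest %% nrow(su)) + 1L
  i_t <- (rest %/% nrow(su)) + 1L

  smiles <- mapply(assemble_smiles, sc$smiles[i_sc], su$smiles[i_a], su$smiles[i_t],
                   USE.NAMES = FALSE)
  lipo <- sc$lipo[i_sc] + su$lipo[i_a] + su$lipo[i_t]
  polar <- sc$polar[i_sc] + su$polar[i_a] + su$polar[i_t]
  rings <- sc$rings[i_sc]

  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  u <- config$beta[1] * zs(lipo) + config$beta[2] * zs(polar) +
    config$image_signal_weight * zs(rings)
  endpoint <- exp(u + eps)

  ids <- sprintf("SYN%04d", seq_len(config$n_compounds))
  records <- lapply(seq_len(config$n_compounds), function(i)
    compound_record(ids[i], smiles[i], endpoint[i]))
  records <- label_compounds(records, config$threshold)
  structure(records,
            rejected = data.frame(input = character(), reason = character()),
            generative_terms = data.frame(compound_id = ids, lipo = lipo,
                                          polar = polar, rings = rings, u = u),
            synth_config = config,
            class = "compound_library")
}

#' Assign binary class labels by thresholding the endpoint
#'
#' `class_label` is 1 iff `endpoint > threshold`; a value exactly at the
#' threshold is labelled 0.
#'
#' @param records list of [compound_record()]s with endpoints.
#' @param threshold class boundary on the endpoint scale.
#' @return the records with `class_label` set.
#' @export
label_compounds <- function(records, threshold) {
  out <- lapply(records, function(r) {
    if (is.na(r$endpoint)) stop("missing endpoint for ", r$compound_id)
    r$class_label <- as.integer(r$endpoint > threshold)
    r
  })
  attributes(out) <- attributes(records)
  out
}

#' Descriptor names withheld from synthetic benchmark regressions
#'
#' When the generator's image-signal weight is positive, the ring-count
#' term must stay out of the descriptor table for the benchmark to probe
#' whether the image channel adds information. Ring count leaks through
#' every size- and whole-molecule-lipophilicity descriptor, so those
#' structural surrogates are excluded together (via the leakage mechanism
#' of [filter_descriptors()]).
#'
#' @return character vector of descriptor names.
#' @export
synthetic_withheld_descriptors <- function() {
  c("ring_count", "aromatic_ring_count", "n_aromatic_atoms", "n_aromatic_bonds",
    "n_heavy_atoms", "n_atoms", "n_carbon", "n_hydrogen", "n_bonds",
    "n_single_bonds", "n_double_bonds", "n_triple_bonds",
    "mw", "slogp", "logd_proxy", "molar_refractivity", "hba_broad",
    "rgyr_3d", "span_3d", "asphericity_3d", "pmi_ratio_1", "pmi_ratio_2")
}
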