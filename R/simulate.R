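#' COG functional categories used by the synthetic community generator
#' @export
COG_CATEGORIES <- c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M", "O", "P")

#' KEGG-style pathway identifiers used by the synthetic community generator
#'
#' Twelve pathway ids in KEGG map notation; `ko00010` is
#' glycolysis/gluconeogenesis, the pathway whose enzyme balance the
#' drug-response analysis examines in detail.
#' @export
KEGG_PATHWAYS <- c("ko00010", "ko00020", "ko00051", "ko00052", "ko00190",
                   "ko00250", "ko00260", "ko00500", "ko00620", "ko02010",
                   "ko02020", "ko03010")

#' Configuration for the synthetic metaproteome generator
#'
#' Bundles every knob of the ground-truthed community and dataset simulator
#' and validates it. The defaults describe a realistic desk-scale gut
#' community: a handful of phyla, log-normally distributed species biomass,
#' moderate peptide degeneracy, multiplicative measurement noise and a small
#' detection-limit truncation.
#'
#' @param n_phyla,n_genera,n_species Number of phyla, genera and species;
#'   must satisfy `n_species >= n_genera >= n_phyla`.
#' @param proteins_per_species Proteins in the catalog per species.
#' @param peptides_per_protein Peptides generated per protein.
#' @param frac_peptides_shared_within_genus Fraction of peptides shared by
#'   proteins of at least two species of one genus (resolve to genus under
#'   lowest common ancestor).
#' @param frac_peptides_shared_across_phyla Fraction of peptides shared
#'   across phyla (resolve only to superkingdom).
#' @param noise_sigma Standard deviation of log-intensity measurement noise.
#' @param subject_sigma Standard deviation of the per-subject log-normal
#'   biological effect on species abundance; frozen per (subject, species)
#'   so that both study arms of a subject share it.
#' @param detection_quantile Fraction of the lowest nonzero peptide
#'   intensities per sample set to zero (not detected).
#' @param treatment_effects Data frame with columns `target`, `level`
#'   (one of `"species"`, `"genus"`, `"phylum"`, `"pathway"`) and `effect`
#'   (multiplicative, > 0), applied to treated samples only. `NULL` for none.
#' @param total_intensity Scale factor bringing intensities to a
#'   mass-spectrometry-like magnitude; has no effect on any relative result.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_phyla = 4, n_genera = 10, n_species = 30,
                       proteins_per_species = 20, peptides_per_protein = 5,
                       frac_peptides_shared_within_genus = 0.15,
                       frac_peptides_shared_across_phyla = 0.05,
                       noise_sigma = 0.2, subject_sigma = 0.3,
                       detection_quantile = 0.05,
                       treatment_effects = NULL,
                       total_intensity = 1e9, seed = 1L) {
  cfg <- list(
    n_phyla = n_phyla, n_genera = n_genera, n_species = n_species,
    proteins_per_species = proteins_per_species,
    peptides_per_protein = peptides_per_protein,
    frac_peptides_shared_within_genus = frac_peptides_shared_within_genus,
    frac_peptides_shared_across_phyla = frac_peptides_shared_across_phyla,
    noise_sigma = noise_sigma, subject_sigma = subject_sigma,
    detection_quantile = detection_quantile,
    treatment_effects = treatment_effects,
    total_intensity = total_intensity, seed = as.integer(seed)
  )
  check_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      abort(paste0("invalid configuration: `", field,
                   "` must be a positive integer"),
            class = "mipror_config_error")
  }
  for (f in c("n_phyla", "n_genera", "n_species", "proteins_per_species",
              "peptides_per_protein")) check_count(f)
  check_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      abort(paste0("invalid configuration: `", field, "` must lie in [0, 1]"),
            class = "mipror_config_error")
  }
  for (f in c("frac_peptides_shared_within_genus",
              "frac_peptides_shared_across_phyla",
              "detection_quantile")) check_frac(f)
  for (f in c("noise_sigma", "subject_sigma")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      abort(paste0("invalid configuration: `", f, "` must be >= 0"),
            class = "mipror_config_error")
  }
  if (!(n_species >= n_genera && n_genera >= n_phyla))
    abort("invalid configuration: need `n_species` >= `n_genera` >= `n_phyla`",
          class = "mipror_config_error")
  if (!is.null(treatment_effects)) {
    te <- as_tibble(treatment_effects)
    need <- c("target", "level", "effect")
    if (!all(need %in% names(te)))
      abort("invalid configuration: `treatment_effects` needs columns target, level, effect",
            class = "mipror_config_error")
    if (!all(te$level %in% c("species", "genus", "phylum", "pathway")))
      abort("invalid configuration: `treatment_effects$level` must be species, genus, phylum or pathway",
            class = "mipror_config_error")
    if (any(!is.finite(te$effect) | te$effect <= 0))
      abort("invalid configuration: `treatment_effects$effect` must be > 0",
            class = "mipror_config_error")
    cfg$treatment_effects <- te
  }
  structure(cfg, class = "sim_config")
}

#' Generate a ground-truthed synthetic community
#'
#' Builds the fixed, sample-independent part of a synthetic metaproteomic
#' study: a taxonomic tree over seven ranks, a protein catalog (one species
#' of origin and one COG category per protein, optional KEGG pathway and
#' enzyme annotations), a peptide-to-protein map with controlled taxonomic
#' degeneracy, log-normal species base abundances summing to one, and
#' per-species COG expression profiles (Dirichlet draws summing to one).
#' Peptide ionization efficiencies are drawn once here and frozen, so
#' replicate samples later differ only by biology and measurement noise.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_community`: a list with elements
#'   `taxonomy` (species lineages over the seven ranks), `proteins`,
#'   `peptides` (with a `Proteins` list-column), `species_abundance`,
#'   `function_profiles` and the `config`.
#' @export
sim_community <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, {
    n_ph <- config$n_phyla; n_ge <- config$n_genera; n_sp <- config$n_species

    phylum_of_genus <- c(seq_len(n_ph),
                         if (n_ge > n_ph)
                           sample(n_ph, n_ge - n_ph, replace = TRUE))
    genus_of_species <- c(seq_len(n_ge),
                          if (n_sp > n_ge)
                            sample(n_ge, n_sp - n_ge, replace = TRUE))
    species <- sprintf("Species_%03d", seq_len(n_sp))
    taxonomy <- tibble(
      Taxon = species,
      Superkingdom = "Bacteria",
      Phylum  = sprintf("Phylum_%02d", phylum_of_genus[genus_of_species]),
      Class   = sprintf("Class_%02d",  phylum_of_genus[genus_of_species]),
      Order   = sprintf("Order_%02d",  phylum_of_genus[genus_of_species]),
      Family  = sprintf("Family_%02d", genus_of_species),
      Genus   = sprintf("Genus_%02d",  genus_of_species),
      Species = species
    )

    base <- rlnorm(n_sp, 0, 1.5)
    species_abundance <- tibble(Species = species,
                                base_abundance = base / sum(base))

    prof <- t(vapply(seq_len(n_sp), function(i) {
      g <- rgamma(length(COG_CATEGORIES), shape = 0.6)
      g / sum(g)
    }, numeric(length(COG_CATEGORIES))))
    colnames(prof) <- COG_CATEGORIES
    function_profiles <- bind_cols(tibble(Species = species),
                                   as_tibble(prof))

    n_prot <- n_sp * config$proteins_per_species
    prot_species_idx <- rep(seq_len(n_sp), each = config$proteins_per_species)
    cog <- vapply(prot_species_idx, function(i)
      sample(COG_CATEGORIES, 1, prob = prof[i, ]), character(1))
    n_pw <- sample(0:2, n_prot, replace = TRUE, prob = c(0.4, 0.45, 0.15))
    pw <- vapply(n_pw, function(k)
      if (k == 0) "" else
        paste(sort(sample(KEGG_PATHWAYS, k)), collapse = ";"),
      character(1))
    enz <- vapply(pw, function(p) {
      if (p == "") return("")
      first <- strsplit(p, ";", fixed = TRUE)[[1]][1]
      sprintf("EC:%d.%d", match(first, KEGG_PATHWAYS), sample(6, 1))
    }, character(1), USE.NAMES = FALSE)
    proteins <- tibble(
      ProteinGroup = sprintf("PG_%04d", seq_len(n_prot)),
      Species = species[prot_species_idx],
      COG = cog, KEGG_Pathway = pw, Enzyme = enz,
      weight = rlnorm(n_prot, 0, 1)
    )

    n_pep <- n_prot * config$peptides_per_protein
    owner <- rep(seq_len(n_prot), each = config$peptides_per_protein)
    partners <- map(seq_len(n_pep), function(i) integer(0))

    genus_sizes <- table(genus_of_species)
    multi_sp_genus <- as.integer(names(genus_sizes)[genus_sizes >= 2])
    n_wg <- round(config$frac_peptides_shared_within_genus * n_pep)
    n_xp <- round(config$frac_peptides_shared_across_phyla * n_pep)
    eligible_wg <- which(genus_of_species[prot_species_idx[owner]] %in%
                           multi_sp_genus)
    if (n_wg > length(eligible_wg)) {
      warn("fewer genus-shareable peptides than requested; sharing all eligible")
      n_wg <- length(eligible_wg)
    }
    idx_wg <- if (n_wg > 0) sample(eligible_wg, n_wg) else integer(0)
    pool_xp <- setdiff(seq_len(n_pep), idx_wg)
    if (n_xp > 0 && n_ph < 2)
      abort("invalid configuration: `frac_peptides_shared_across_phyla` > 0 needs `n_phyla` >= 2",
            class = "mipror_config_error")
    idx_xp <- if (n_xp > 0) sample(pool_xp, n_xp) else integer(0)

    prot_genus <- genus_of_species[prot_species_idx]
    prot_phylum <- phylum_of_genus[prot_genus]
    for (i in idx_wg) {
      g <- prot_genus[owner[i]]
      cand <- which(prot_genus == g &
                      prot_species_idx != prot_species_idx[owner[i]])
      partners[[i]] <- cand[sample.int(length(cand), 1)]
    }
    for (i in idx_xp) {
      ph <- prot_phylum[owner[i]]
      cand <- which(prot_phylum != ph)
      partners[[i]] <- cand[sample.int(length(cand), 1)]
    }

    peptides <- tibble(
      Peptide = sprintf("Pep_%05d", seq_len(n_pep)),
      Proteins = map2(owner, partners, function(o, p)
        proteins$ProteinGroup[sort(unique(c(o, p)))]),
      ionization = rlnorm(n_pep, 0, 0.5)
    )

    # Calibrate expression weights so that each species' total
    # species-unique peptide response (ionization x weight) is identical.
    # This makes summed peptide intensity an unbiased biomass proxy -- the
    # working assumption of intensity-based biomass estimation -- so the
    # noise-free planted abundances are exactly recoverable downstream.
    single <- lengths(peptides$Proteins) == 1
    owner_single <- owner[single]
    load <- rowsum(peptides$ionization[single] *
                     proteins$weight[owner_single],
                   group = proteins$Species[owner_single])
    scale_sp <- setNames(mean(load) / load[, 1], rownames(load))
    sfac <- scale_sp[proteins$Species]
    sfac[is.na(sfac)] <- 1
    proteins$weight <- proteins$weight * unname(sfac)

    structure(list(taxonomy = taxonomy, proteins = proteins,
                   peptides = peptides,
                   species_abundance = species_abundance,
                   function_profiles = function_profiles,
                   config = config),
              class = "sim_community")
  })
}

#' Build the sample layout of a culture-stability study
#'
#' One baseline (inoculum, 0 h) group per subject plus cultured samples at
#' each later timepoint in each medium, with technical replicates. The
#' defaults mirror a typical design for assessing whether an in vitro
#' culture maintains the inoculum's profile: three subjects, timepoints 0,
#' 9, 24, 34 and 48 h, two media, four technical replicates.
#'
#' @param n_subjects Number of subjects (stool donors).
#' @param timepoints Culture timepoints in hours; must include `baseline`.
#' @param media Character vector of culture medium names.
#' @param n_replicates Technical replicates per subject/timepoint/medium.
#' @param baseline Baseline timepoint (the inoculum), default 0.
#' @return A tibble with columns Sample, Subject, Timepoint, Arm, Condition,
#'   Replicate and a logical Treated column (all `FALSE`).
#' @export
design_stability <- function(n_subjects = 3, timepoints = c(0, 9, 24, 34, 48),
                             media = c("MiPro", "BCM"), n_replicates = 4,
                             baseline = 0) {
  if (!baseline %in% timepoints)
    abort("`timepoints` must include the baseline timepoint")
  subj <- sprintf("V%d", seq_len(n_subjects))
  grid <- bind_rows(
    tidyr::expand_grid(Subject = subj, Timepoint = baseline,
                       Condition = "baseline",
                       Replicate = seq_len(n_replicates)),
    tidyr::expand_grid(Subject = subj,
                       Timepoint = setdiff(timepoints, baseline),
                       Condition = media,
                       Replicate = seq_len(n_replicates))
  )
  grid |>
    mutate(Arm = "in_vitro", Treated = FALSE,
           Sample = sprintf("%s_%s_t%02d_r%d", .data$Subject,
                            .data$Condition, .data$Timepoint,
                            .data$Replicate)) |>
    select("Sample", "Subject", "Timepoint", "Arm", "Condition",
           "Replicate", "Treated")
}

#' Build the sample layout of a paired in vitro / in vivo drug study
#'
#' Each subject contributes an untreated and a treated culture (in vitro
#' arm, 24 h) and an untreated baseline plus treated samples at each in
#' vivo timepoint. The defaults mirror a five-subject metformin study with
#' in vivo sampling at days 14 and 28.
#'
#' @param n_subjects Number of subjects.
#' @param invivo_timepoints In vivo treated timepoints (days).
#' @param invitro_timepoint In vitro culture duration (hours), default 24.
#' @param n_replicates Replicates per condition.
#' @return A tibble in the same layout as [design_stability()], with
#'   `Treated` marking drug-exposed samples.
#' @export
design_drug_response <- function(n_subjects = 5, invivo_timepoints = c(14, 28),
                                 invitro_timepoint = 24, n_replicates = 1) {
  subj <- sprintf("M%d", seq_len(n_subjects))
  rows <- bind_rows(
    tidyr::expand_grid(Subject = subj, Arm = "in_vitro",
                       Timepoint = invitro_timepoint,
                       Treated = c(FALSE, TRUE),
                       Replicate = seq_len(n_replicates)),
    tidyr::expand_grid(Subject = subj, Arm = "in_vivo", Timepoint = 0,
                       Treated = FALSE, Replicate = seq_len(n_replicates)),
    tidyr::expand_grid(Subject = subj, Arm = "in_vivo",
                       Timepoint = invivo_timepoints, Treated = TRUE,
                       Replicate = seq_len(n_replicates))
  )
  rows |>
    mutate(Condition = ifelse(.data$Treated, "treated", "untreated"),
           Sample = sprintf("%s_%s_t%02d_%s_r%d", .data$Subject,
                            ifelse(.data$Arm == "in_vitro", "iv", "vv"),
                            .data$Timepoint,
                            ifelse(.data$Treated, "trt", "ctl"),
                            .data$Replicate)) |>
    select("Sample", "Subject", "Timepoint", "Arm", "Condition",
           "Replicate", "Treated")
}

# Per-species multiplicative treatment effect implied by the configured
# treatment_effects rows (species/genus/phylum levels only).
species_treatment_multiplier <- function(community, effects) {
  n_sp <- nrow(community$taxonomy)
  mult <- rep(1, n_sp)
  if (is.null(effects)) return(mult)
  for (k in seq_len(nrow(effects))) {
    lv <- effects$level[k]
    if (lv == "pathway") next
    col <- switch(lv, species = "Species", genus = "Genus", phylum = "Phylum")
    hit <- community$taxonomy[[col]] == effects$target[k]
    mult[hit] <- mult[hit] * effects$effect[k]
  }
  mult
}

protein_treatment_multiplier <- function(community, effects) {
  n_prot <- nrow(community$proteins)
  mult <- rep(1, n_prot)
  if (is.null(effects)) return(mult)
  pw <- strsplit(community$proteins$KEGG_Pathway, ";", fixed = TRUE)
  for (k in seq_len(nrow(effects))) {
    if (effects$level[k] != "pathway") next
    hit <- vapply(pw, function(p) effects$target[k] %in% p, logical(1))
    mult[hit] <- mult[hit] * effects$effect[k]
  }
  mult
}

#' Simulate a metaproteomic dataset from a synthetic community
#'
#' Produces the post-search tables a metaproteomics search engine would
#' emit, with known ground truth. Per sample, species abundance is the
#' community base abundance times a frozen per-subject log-normal effect
#' and, in treated samples, the configured multiplicative treatment
#' effects. Protein intensity is species abundance times the catalog
#' expression weight times multiplicative log-normal noise; peptide
#' intensity is the sum of its parent proteins' intensities times the
#' peptide's frozen ionization efficiency; protein-group LFQ is the sum of
#' its member peptides' intensities (before missingness). Finally the
#' lowest `detection_quantile` of nonzero peptide intensities in each
#' sample are set to zero, emulating a detection limit.
#'
#' @param community A [sim_community()] object.
#' @param design A study design tibble, e.g. from [design_stability()] or
#'   [design_drug_response()]. A logical `Treated` column marks samples the
#'   treatment effects apply to (absent means untreated).
#' @param config Simulation configuration; defaults to the community's own.
#' @return A list with elements `dataset` (a validated [mipro_dataset()])
#'   and `truth`, a tibble (Species, Sample, true_relative_abundance) whose
#'   per-sample values sum to one.
#' @export
sim_dataset <- function(community, design, config = community$config) {
  stopifnot(inherits(community, "sim_community"))
  design <- as_tibble(design)
  if (nrow(design) == 0) abort("study design lists no samples")
  if (!"Treated" %in% names(design))
    design$Treated <- design$Condition == "treated"

  taxo <- community$taxonomy
  prot <- community$proteins
  pept <- community$peptides
  n_sp <- nrow(taxo); n_prot <- nrow(prot); n_pep <- nrow(pept)
  n_s <- nrow(design)

  with_seed(config$seed + 1L, {
    subjects <- sort(unique(design$Subject))
    subj_eff <- matrix(
      exp(rnorm(n_sp * length(subjects), 0, config$subject_sigma)),
      nrow = n_sp, dimnames = list(taxo$Taxon, subjects))

    sp_mult <- species_treatment_multiplier(community,
                                            config$treatment_effects)
    pr_mult <- protein_treatment_multiplier(community,
                                            config$treatment_effects)

    abund <- vapply(seq_len(n_s), function(j) {
      a <- community$species_abundance$base_abundance *
        subj_eff[, design$Subject[j]]
      if (design$Treated[j]) a <- a * sp_mult
      a
    }, numeric(n_sp))
    dimnames(abund) <- list(taxo$Taxon, design$Sample)

    sp_idx <- match(prot$Species, taxo$Taxon)
    noise <- matrix(exp(rnorm(n_prot * n_s, 0, config$noise_sigma)),
                    nrow = n_prot)
    P <- abund[sp_idx, , drop = FALSE] * prot$weight * noise
    for (j in seq_len(n_s))
      if (design$Treated[j]) P[, j] <- P[, j] * pr_mult
    P <- P * config$total_intensity

    pep_prot <- map2(seq_len(n_pep), pept$Proteins, function(i, pr)
      cbind(i, match(pr, prot$ProteinGroup)))
    ij <- do.call(rbind, pep_prot)
    M <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                              dims = c(n_pep, n_prot))
    Q <- as.matrix(M %*% P) * pept$ionization
    L <- as.matrix(Matrix::t(M) %*% Q)          # LFQ before missingness

    if (config$detection_quantile > 0) {
      for (j in seq_len(n_s)) {
        nz <- which(Q[, j] > 0)
        k <- floor(config$detection_quantile * length(nz))
        if (k > 0) Q[nz[order(Q[nz, j])[seq_len(k)]], j] <- 0
      }
    }

    colnames(Q) <- paste0("Intensity.", design$Sample)
    colnames(L) <- paste0("LFQ.", design$Sample)

    peptide_tbl <- bind_cols(
      tibble(Peptide = pept$Peptide,
             ProteinGroups = map_chr(pept$Proteins, paste, collapse = ";")),
      as_tibble(Q))
    protein_tbl <- bind_cols(
      prot |> select("ProteinGroup", "Species", "COG", "KEGG_Pathway",
                     "Enzyme"),
      as_tibble(L))

    rel <- sweep(abund, 2, colSums(abund), "/")
    truth <- matrix_to_tbl(rel, "Species") |>
      tidyr::pivot_longer(-"Species", names_to = "Sample",
                          values_to = "true_relative_abundance")

    list(dataset = mipro_dataset(peptide_tbl, protein_tbl, taxo,
                                 design |> select(-"Treated")),
         truth = truth)
  })
}
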