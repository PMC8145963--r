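# Synthetic-study generator: a seeded emulation of a genome-scale
# knock-out/overexpression lipidomics screen (116 constructs, +/- 0.5%
# n-butanol, triplicate cultures, WT and empty-vector controls on every
# plate) producing aligned mz/rt feature tables, OD600 curves, sample
# metadata and a ground-truth ledger for recovery tests.

# Gene pool for the default construct set; loosely the E. coli
# lipid-related gene complement (fatty acid synthesis/degradation,
# phospholipid synthesis and modification, glycerol metabolism).
.GENE_POOL <- c(
  "cfa", "fabH", "clsB", "aas", "clsA", "pldA", "fadD", "fadL", "fabF",
  "fabA", "fabB", "fabD", "fabG", "fabI", "fabZ",
  "accA", "accB", "accC", "accD",
  "clsC", "pssA", "psd", "pgsA", "pgpA", "pgpB", "pgpC", "cdsA",
  "dgkA", "plsB", "plsC", "plsX", "plsY", "pldB",
  "fadA", "fadB", "fadE", "fadI", "fadJ", "fadR",
  "tesA", "tesB", "ybgC", "glpA", "glpB", "glpC",
  "glpF", "glpQ", "glpT", "gpsA", "aidB", "envC", "cdh", "pldC",
  "glpD", "glpK", "glpR",
  "lpxA", "lpxB", "lpxC", "lpxD"
)

# Growth-only effector genes: strong growth phenotypes, no planted
# lipidome effect beyond the generic background.
.GROWTH_GENES <- c("glpD", "glpK", "glpR")

default_constructs <- function(n_constructs = 116) {
  pool <- .GENE_POOL
  # interleave OV and KO so truncated construct sets keep both types;
  # the last 4 genes are overexpression-only (60 OV + 56 KO = 116)
  rows <- purrr::map(seq_along(pool), function(i) {
    r <- tibble(gene = pool[i], construct_type = "OV")
    if (i <= 56) r <- dplyr::bind_rows(r, tibble(gene = pool[i],
                                                 construct_type = "KO"))
    r
  })
  all <- dplyr::bind_rows(rows)
  if (n_constructs > nrow(all)) {
    abort(sprintf("At most %d default constructs available.", nrow(all)))
  }
  all[seq_len(n_constructs), ]
}

# The ten-species marker panel planted as ground truth, mirroring the
# species set a construct x butanol classifier keys on: abundant PE
# species, cyclopropane-carrying PGs, headgroup acylates and the
# butanol-specific PBut.
.DEFAULT_MARKERS <- c(
  "PE 34:1", "PE 32:1", "PE 36:2", "PG 35:0c1", "PG 31:0c1",
  "aPG 50:2", "aPE 49:0c1", "aPG 49:1c1", "PBut 33:0c1", "aPE 50:1"
)

#' Configuration of a synthetic lipidome study
#'
#' All knobs of the synthetic-study generator. The defaults emulate the
#' study design the analysis targets: 116 genetic constructs (gene
#' knock-outs and overexpressors), triplicate cultures with and without
#' 0.5% n-butanol, wild-type and empty-vector controls replicated across
#' plates, ~230 lipid species over 11 phospholipid classes with
#' abundances spanning ~25% down to 0.01%, construct-specific
#' multiplicative composition effects, butanol effects (halved growth
#' rate, reduced cyclopropane content, PBut formation in ClsB
#' overexpressors), isotope envelopes, decoy noise features and logistic
#' OD600 curves on a 5-minute grid.
#'
#' @param seed Integer seed; every draw of the generator derives from it.
#' @param n_constructs Number of genetic constructs (default 116).
#' @param replicates Cultures per construct per condition (default 3).
#' @param control_replicates Cultures per control (WT, EV) per condition
#'   (default 9: controls sit on every plate).
#' @param butanol_arms Simulate the paired +butanol arm (default TRUE).
#' @param db [db_config()] used for species enumeration.
#' @param class_weights Named baseline class abundances (percent scale).
#' @param chain_center,chain_sd Per-chain carbon number distribution of
#'   the baseline composition.
#' @param mod_decay Exponential decay of abundance per double bond /
#'   ring.
#' @param dirichlet_concentration Precision of the Dirichlet draw around
#'   the baseline spectrum.
#' @param marker_species Planted marker panel (default: ten species
#'   across PE, PG, aPE, aPG and PBut).
#' @param marker_effect_sd Log-scale magnitude of a gene's effect on its
#'   reporter markers (default 1.3: typical fold changes of ~4, extremes
#'   of 10-30x across the construct set, the order such screens report).
#' @param generic_effect_sd Log-scale SD of background effects every
#'   construct exerts on a random species subset (default 0.05).
#' @param bio_cv Between-replicate biological variability of species
#'   abundances (log-scale SD, default 0.02; cultures of one construct
#'   are highly consistent).
#' @param n_targets Background target species per construct (default 8).
#' @param butanol_mu_factor Growth-rate multiplier under butanol
#'   (default 0.5: 50% inhibition).
#' @param butanol_cyclopropane_factor Multiplier on cyclopropane species
#'   under butanol (default 0.6; their unsaturated precursors rise
#'   correspondingly).
#' @param pbut_fraction PBut mass fraction formed in ClsB overexpressors
#'   grown on butanol (default 0.03).
#' @param curated_effects Apply the curated gene-specific biology (cfa
#'   on cyclopropane species, fabH on chain length/unsaturation, aas on
#'   headgroup acylates, clsA/clsB on cardiolipins, pldA on aPG);
#'   disable for a pure planted-marker study.
#' @param total_signal Expected total MS signal per sample (arbitrary
#'   counts, default 1e6).
#' @param emit_isotopes Emit A+1/A+2 isotopologue features (default
#'   TRUE; disable for an envelope-free table).
#' @param feature_cv Multiplicative measurement noise CV on species
#'   intensities (default 0.02, the replicate spread typical of
#'   percent-normalized HILIC-MS lipidomes).
#' @param mz_jitter_sd,rt_jitter_sd Feature-position jitter (Th /
#'   minutes).
#' @param decoy_rate Decoy (unassignable noise) features per real
#'   species (default 0.2).
#' @param detection_limit Intensity below which a cell is not detected
#'   (default 200 counts), exercising forced integration downstream.
#' @param mu_wt,K_wt,od0 Wild-type growth parameters: maximum specific
#'   growth rate (1/h), carrying capacity and inoculum OD600.
#' @param t_hours,dt_min OD sampling span and interval.
#' @param od_cv Multiplicative OD measurement noise (default 0.01).
#' @param rep_mu_cv,rep_K_cv Biological replicate variability of growth
#'   parameters.
#' @param growth_effect_fraction Fraction of constructs with a true
#'   growth-rate effect (default 42/116).
#' @param growth_effect_sd Log-scale SD of those effects (default 0.2).
#' @param failure_rate Per-culture probability of growth failure
#'   (default 0.01; failed wells stay below the OD 0.2 QC bar).
#' @return List of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         n_constructs = 116,
                         replicates = 3,
                         control_replicates = 9,
                         butanol_arms = TRUE,
                         db = db_config(),
                         class_weights = c(
                           PE = 72, PG = 18, CL = 4, PA = 1, `CDP-DAG` = 0.8,
                           PS = 0.5, PGP = 0.4, DLCL = 0.4, aPE = 1.2,
                           aPG = 1.3, PBut = 0),
                         chain_center = 16.75, chain_sd = 1.3,
                         mod_decay = 1.2,
                         dirichlet_concentration = 5000,
                         marker_species = .DEFAULT_MARKERS,
                         marker_effect_sd = 1.3,
                         generic_effect_sd = 0.05, n_targets = 8,
                         bio_cv = 0.02,
                         butanol_mu_factor = 0.5,
                         butanol_cyclopropane_factor = 0.6,
                         pbut_fraction = 0.03,
                         curated_effects = TRUE,
                         total_signal = 1e6, feature_cv = 0.02,
                         mz_jitter_sd = 0.005, rt_jitter_sd = 0.03,
                         decoy_rate = 0.2, detection_limit = 200,
                         emit_isotopes = TRUE,
                         mu_wt = 0.9, K_wt = 0.75, od0 = 0.02,
                         t_hours = 16, dt_min = 5, od_cv = 0.01,
                         rep_mu_cv = 0.02, rep_K_cv = 0.03,
                         growth_effect_fraction = 42 / 116,
                         growth_effect_sd = 0.2,
                         failure_rate = 0.01) {
  if (is.null(seed) || is.na(seed)) abort("A seed is mandatory.")
  cfg <- as.list(environment())
  stopifnot(cfg$replicates >= 1, cfg$feature_cv >= 0, cfg$od_cv >= 0,
            cfg$decoy_rate >= 0, cfg$failure_rate >= 0,
            cfg$mu_wt > 0, cfg$K_wt > cfg$od0, cfg$od0 > 0)
  structure(cfg, class = "study_config")
}

# Baseline percent composition over the canonical species of the
# database: class weight x per-chain carbon bell x per-modification
# decay, roughened by a Dirichlet draw.
baseline_composition <- function(db, config) {
  sp <- db[db$canonical, , drop = FALSE]
  w_class <- config$class_weights[sp$class]
  w_class[is.na(w_class)] <- 0
  per_chain <- sp$total_carbons / sp$n_chains
  m <- sp$double_bonds + sp$cyclopropane
  shape <- exp(-((per_chain - config$chain_center) / config$chain_sd)^2 / 2) *
    exp(-config$mod_decay * m)
  w <- unname(w_class) * shape
  # within-class renormalization so class totals follow class_weights
  for (cl in unique(sp$class)) {
    i <- sp$class == cl
    tot <- sum(w[i])
    if (tot > 0) w[i] <- w[i] / tot * config$class_weights[[cl]]
  }
  w <- w / sum(w)
  # planted markers must be quantifiable: keep their baseline above the
  # bottom of the reported marker abundance range (~0.1%)
  mk <- match(intersect(config$marker_species, sp$name), sp$name)
  mk <- mk[sp$class[mk] != "PBut"]
  w[mk] <- pmax(w[mk], 0.0012)
  w <- w / sum(w)
  g <- stats::rgamma(length(w), shape = config$dirichlet_concentration * w,
                     rate = 1)
  g[w == 0] <- 0
  x <- 100 * g / sum(g)
  stats::setNames(x, sp$name)
}

# Multiplicative per-construct effect vectors (named by species),
# combining curated biology (cfa, fabH, aas, clsA, pldA, clsB) with
# strong planted marker drivers and a weak generic background.
build_effect_map <- function(db, config, constructs, baseline) {
  sp <- db[db$canonical, , drop = FALSE]
  species <- sp$name
  cyclo <- species[sp$cyclopropane >= 1]
  # unsaturated precursors of the cyclopropane species: one carbon less,
  # one double bond more (the ring is laid onto a double bond and adds a
  # methylene)
  prec <- build_species_name(
    sp$class[sp$cyclopropane >= 1],
    sp$total_carbons[sp$cyclopropane >= 1] - 1L,
    sp$double_bonds[sp$cyclopropane >= 1] + 1L, 0L)
  prec <- intersect(prec, species)
  per_chain <- stats::setNames(sp$total_carbons / sp$n_chains, species)
  db_per_chain <- stats::setNames(sp$double_bonds / sp$n_chains, species)

  # The markers jointly fingerprint the construct set: every lipid gene
  # reports on a pair of markers (round-robin over the panel, so the
  # markers carry complementary information and none is dispensable)
  # with a fixed fold change whose direction flips between
  # overexpression and knock-out. Sign patterns are drawn without
  # replacement per pair, so genes sharing a reporter pair always
  # differ in at least one direction. PBut species carry no baseline
  # (butanol-induced only) and cannot report on construct identity.
  markers <- intersect(config$marker_species, species)
  reporters <- markers[sp$class[match(markers, species)] != "PBut"]
  lipid_genes <- setdiff(unique(constructs$gene), .GROWTH_GENES)
  patterns <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  pair_used <- list()
  driver <- list()
  for (gi in seq_along(lipid_genes)) {
    rep_idx <- ((2 * (gi - 1) + 0:1) %% length(reporters)) + 1
    pair_key <- paste(sort(rep_idx), collapse = "-")
    avail <- setdiff(seq_along(patterns), pair_used[[pair_key]])
    if (length(avail) == 0) {
      pair_used[[pair_key]] <- integer()
      avail <- seq_along(patterns)
    }
    pick <- if (length(avail) == 1) avail else sample(avail, 1)
    pair_used[[pair_key]] <- c(pair_used[[pair_key]], pick)
    driver[[gi]] <- tibble(
      gene = lipid_genes[gi],
      marker = reporters[rep_idx],
      log_effect = patterns[[pick]] * config$marker_effect_sd)
  }
  driver <- dplyr::bind_rows(driver)

  effects <- list()
  for (i in seq_len(nrow(constructs))) {
    gene <- constructs$gene[i]
    type <- constructs$construct_type[i]
    key <- paste0(gene, ":", type)
    mult <- stats::setNames(rep(1, length(species)), species)
    marker_mult <- stats::setNames(rep(1, length(markers)), markers)
    sign <- if (type == "OV") 1 else -1

    if (!config$curated_effects) {
      # planted markers only
    } else if (gene == "cfa") {
      mult[cyclo] <- mult[cyclo] * if (type == "OV") 3.5 else 0.08
      mult[prec] <- mult[prec] * if (type == "OV") 0.12 else 4
    } else if (gene == "fabH") {
      # overexpression initiates more chains -> shorter, more saturated
      mult <- mult * exp(-sign * 0.5 * (per_chain - config$chain_center)) *
        exp(-sign * 1.2 * db_per_chain)
    } else if (gene == "aas") {
      idx <- species[sp$class %in% c("aPE", "aPG")]
      mult[idx] <- mult[idx] * if (type == "OV") 4 else 0.2
    } else if (gene == "clsA") {
      idx <- species[sp$class %in% c("CL", "DLCL")]
      mult[idx] <- mult[idx] * if (type == "OV") 2.5 else 0.3
    } else if (gene == "pldA") {
      idx <- species[sp$class == "aPG"]
      mult[idx] <- mult[idx] * if (type == "OV") 2 else 0.6
    } else if (gene == "clsB") {
      idx <- species[sp$class == "CL"]
      mult[idx] <- mult[idx] * if (type == "OV") 1.5 else 0.8
    }

    # the planted markers respond to constructs through the driver map
    # alone (the cfa cyclopropane effect excepted), so their construct
    # signature is exactly the planted one
    if (gene != "cfa") mult[markers] <- 1

    if (!gene %in% .GROWTH_GENES) {
      tgt <- sample(setdiff(species, c(species[sp$class == "PBut"],
                                       markers)),
                    config$n_targets)
      mult[tgt] <- mult[tgt] * exp(stats::rnorm(length(tgt), 0,
                                                config$generic_effect_sd))
      drv <- driver[driver$gene == gene, , drop = FALSE]
      if (nrow(drv) > 0) {
        marker_mult[drv$marker] <- marker_mult[drv$marker] *
          exp(sign * drv$log_effect)
      }
    }
    effects[[key]] <- list(mult = mult, marker_mult = marker_mult)
  }
  list(effects = effects, driver = driver, markers = markers)
}

#' Simulate one true lipidome composition
#'
#' Applies a construct's multiplicative effects and the butanol response
#' to the study baseline and renormalizes to 100%. Butanol reduces
#' cyclopropane-containing species (their unsaturated precursors rise),
#' and in ClsB overexpressors induces phosphatidylbutanol via headgroup
#' exchange with the medium n-butanol; without butanol no PBut is
#' formed.
#'
#' @param baseline Named baseline percent composition (see
#'   [simulate_study()] internals).
#' @param effect Construct effect: list with `mult` (named multiplier
#'   vector over all species) and `marker_mult` (multipliers
#'   redistributing abundance within the marker pool), or `NULL` for
#'   controls.
#' @param butanol Logical: grown on 0.5% n-butanol?
#' @param clsb_ov Logical: is this the ClsB overexpressor?
#' @param config A [study_config()].
#' @param db Database tibble.
#' @return Named percent composition summing to 100.
#' @export
simulate_lipidome <- function(baseline, effect, butanol, clsb_ov, config,
                              db) {
  x <- baseline
  if (!is.null(effect)) {
    x <- x * effect$mult[names(x)]
    # marker-driver effects redistribute abundance within the marker
    # pool (metabolically linked species), so the construct signature
    # lives in the marker ratios rather than in a global scale shift
    mk <- names(effect$marker_mult)
    pre <- sum(x[mk])
    x[mk] <- x[mk] * effect$marker_mult
    if (sum(x[mk]) > 0 && pre > 0) x[mk] <- x[mk] * pre / sum(x[mk])
  }
  sp <- db[match(names(x), db$name), , drop = FALSE]
  if (butanol) {
    cyc <- sp$cyclopropane >= 1
    removed <- sum(x[cyc]) * (1 - config$butanol_cyclopropane_factor)
    x[cyc] <- x[cyc] * config$butanol_cyclopropane_factor
    prec <- build_species_name(sp$class[cyc], sp$total_carbons[cyc] - 1L,
                               sp$double_bonds[cyc] + 1L, 0L)
    pn <- unique(prec[prec %in% names(x)])
    if (length(pn) > 0 && removed > 0 && sum(x[pn]) > 0) {
      x[pn] <- x[pn] + removed * x[pn] / sum(x[pn])
    }
    if (clsb_ov) {
      pbut <- names(x)[sp$class == "PBut"]
      if (length(pbut) > 0) {
        main <- intersect(config$marker_species, pbut)
        main <- if (length(main) > 0) main[1] else pbut[1]
        rest <- setdiff(pbut, main)
        x[main] <- config$pbut_fraction * sum(x)
        if (length(rest) > 0) {
          x[rest] <- config$pbut_fraction * sum(x) * 0.05 / length(rest)
        }
      }
    }
  }
  100 * x / sum(x)
}

#' Simulate an aligned mz/rt feature table
#'
#' Turns true percent compositions into the feature table an LC-MS
#' pre-processing pipeline would deliver: per species a monoisotopic
#' feature at its deprotonated m/z (with position jitter) inside its
#' class retention window, A+1 and A+2 13C isotopologue features scaled
#' by the carbon-binomial envelope, multiplicative intensity noise,
#' a per-cell detection limit, and unassignable decoy features.
#'
#' @param compositions Species x samples matrix of true percent
#'   compositions (rownames = species names).
#' @param db Database tibble.
#' @param config A [study_config()].
#' @return Tibble with columns `mz`, `rt`, then one column per sample;
#'   the number of decoy rows is attached as attribute `n_decoys`.
#' @export
simulate_feature_table <- function(compositions, db, config) {
  sp <- db[match(rownames(compositions), db$name), , drop = FALSE]
  n_s <- ncol(compositions)
  base <- compositions / 100 * config$total_signal
  if (config$feature_cv > 0) {
    base <- base * matrix(exp(stats::rnorm(length(base), 0,
                                           config$feature_cv)),
                          nrow = nrow(base))
  }
  present <- rowSums(base) > 0
  rows <- list()
  for (i in which(present)) {
    rt <- min(max(sp$rt_center[i] + stats::rnorm(1, 0, config$rt_jitter_sd),
                  sp$rt_min[i]), sp$rt_max[i])
    for (k in if (config$emit_isotopes) 0:2 else 0L) {
      inten <- base[i, ] * isotope_ratio(sp$formula[i], k,
                                         p = config$db$p13c)
      inten[inten < config$detection_limit] <- 0
      if (all(inten == 0)) next
      rows[[length(rows) + 1]] <- c(
        mz = sp$mz[i] + k * 1.0033548 +
          stats::rnorm(1, 0, config$mz_jitter_sd),
        rt = rt, inten)
    }
  }
  n_real <- sum(present)
  n_decoys <- stats::rpois(1, config$decoy_rate * n_real)
  canon <- db[db$canonical, , drop = FALSE]
  made <- 0L
  tries <- 0L
  while (made < n_decoys && tries < 50 * n_decoys) {
    tries <- tries + 1L
    mz <- stats::runif(1, config$db$mz_range[1], config$db$mz_range[2])
    rt <- stats::runif(1, 0.2, 3.9)
    clash <- any(abs(canon$mz - mz) <= 0.35 &
                   canon$rt_min - 0.05 <= rt & rt <= canon$rt_max + 0.05)
    if (clash) next
    inten <- ifelse(stats::runif(n_s) < 0.4,
                    exp(stats::rnorm(n_s, log(150), 0.8)), 0)
    inten[inten < config$detection_limit * 0.25] <- 0
    rows[[length(rows) + 1]] <- c(mz = mz, rt = rt,
                                  stats::setNames(inten,
                                                  colnames(compositions)))
    made <- made + 1L
  }
  out <- as_tibble(do.call(rbind, rows))
  names(out) <- c("mz", "rt", colnames(compositions))
  out <- out[order(out$mz), ]
  attr(out, "n_decoys") <- made
  out
}

#' Simulate a logistic OD600 growth curve
#'
#' Closed-form logistic trajectory
#' \eqn{OD(t) = K / (1 + (K/OD_0 - 1) e^{-\mu t})} sampled on a uniform
#' grid with multiplicative measurement noise.
#'
#' @param mu Maximum specific growth rate (1/h).
#' @param K Carrying capacity (OD600).
#' @param od0 Inoculum OD600 (default 0.02, a 1:100 dilution of a
#'   stationary culture).
#' @param t_hours,dt_min Sampling span (h) and interval (min).
#' @param od_cv Multiplicative noise CV (0 for the exact closed form).
#' @return Tibble with `time_min`, `od`.
#' @export
simulate_growth_curve <- function(mu, K, od0 = 0.02, t_hours = 16,
                                  dt_min = 5, od_cv = 0.01) {
  stopifnot(mu > 0, K > od0, od0 > 0)
  t_min <- seq(0, t_hours * 60, by = dt_min)
  od <- K / (1 + (K / od0 - 1) * exp(-mu * t_min / 60))
  if (od_cv > 0) od <- od * exp(stats::rnorm(length(od), 0, od_cv))
  tibble(time_min = t_min, od = od)
}

#' Simulate a full synthetic lipidome study
#'
#' Assembles the complete study: sample metadata (constructs x butanol x
#' replicates, WT/EV controls, plate assignment), true per-sample
#' compositions, the aligned feature table, OD600 curves and a
#' ground-truth ledger. Fully reproducible from `config$seed`.
#'
#' @param config A [study_config()].
#' @return Object of class `synthetic_study`: list with `features`
#'   (feature-table tibble), `od` (wide OD tibble), `metadata`,
#'   `database`, `truth` (list: `baseline`, `compositions`,
#'   `effects`, `marker_species`, `marker_drivers`, `growth`
#'   (per-sample true mu/K), `construct_growth`, `failed_samples`,
#'   `n_decoys`) and `config`.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  db <- lipid_database(config$db)

  constructs <- default_constructs(config$n_constructs)
  butanol_lv <- if (config$butanol_arms) c(0L, 1L) else 0L
  meta <- dplyr::bind_rows(
    tidyr::expand_grid(constructs, butanol = butanol_lv,
                       replicate = seq_len(config$replicates)),
    tidyr::expand_grid(tibble(gene = c("WT", "EV"),
                              construct_type = c("WT", "EV")),
                       butanol = butanol_lv,
                       replicate = seq_len(config$control_replicates))
  )
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  meta$plate <- (seq_len(nrow(meta)) - 1) %/% 96 + 1
  meta <- meta[, c("sample_id", "gene", "construct_type", "butanol",
                   "replicate", "plate")]

  baseline <- baseline_composition(db, config)
  em <- build_effect_map(db, config, constructs, baseline)

  comp <- matrix(0, nrow = length(baseline), ncol = nrow(meta),
                 dimnames = list(names(baseline), meta$sample_id))
  cache <- list()
  for (i in seq_len(nrow(meta))) {
    key <- paste0(meta$gene[i], ":", meta$construct_type[i], ":",
                  meta$butanol[i])
    if (is.null(cache[[key]])) {
      eff_key <- paste0(meta$gene[i], ":", meta$construct_type[i])
      cache[[key]] <- simulate_lipidome(
        baseline, em$effects[[eff_key]],
        butanol = meta$butanol[i] == 1L,
        clsb_ov = meta$gene[i] == "clsB" &&
          meta$construct_type[i] == "OV",
        config = config, db = db)
    }
    x <- cache[[key]]
    if (config$bio_cv > 0) {
      x <- x * exp(stats::rnorm(length(x), 0, config$bio_cv))
    }
    comp[, i] <- 100 * x / sum(x)
  }

  features <- simulate_feature_table(comp, db, config)

  # per-construct growth effects: curated glycerol-metabolism phenotypes
  # plus a random subset of constructs with log-normal effects
  constructs$construct <- paste0(constructs$gene, ":",
                                 constructs$construct_type)
  curated_mu <- c("glpK:OV" = 1.3, "glpR:KO" = 1.25, "glpD:OV" = 0.6,
                  "glpD:KO" = 0.55)
  n_eff <- round(config$growth_effect_fraction * nrow(constructs))
  eff_idx <- which(constructs$construct %in% names(curated_mu))
  extra <- sample(setdiff(seq_len(nrow(constructs)), eff_idx))
  eff_idx <- c(eff_idx, extra[seq_len(max(0, n_eff - length(eff_idx)))])
  mu_mult <- stats::setNames(rep(1, nrow(constructs)),
                             constructs$construct)
  mu_mult[eff_idx] <- exp(stats::rnorm(length(eff_idx), 0,
                                       config$growth_effect_sd))
  hit <- intersect(names(curated_mu), names(mu_mult))
  mu_mult[hit] <- curated_mu[hit]
  k_mult <- stats::setNames(rep(1, nrow(constructs)),
                            constructs$construct)
  k_mult[eff_idx] <- exp(stats::rnorm(length(eff_idx), 0,
                                      config$growth_effect_sd / 2))
  curated_k <- c("glpK:OV" = 1.25, "glpD:KO" = 0.7)
  hit_k <- intersect(names(curated_k), names(k_mult))
  k_mult[hit_k] <- curated_k[hit_k]

  construct_growth <- tibble(
    construct = constructs$construct, gene = constructs$gene,
    construct_type = constructs$construct_type,
    mu_mult = unname(mu_mult), k_mult = unname(k_mult),
    has_mu_effect = seq_len(nrow(constructs)) %in% eff_idx)

  failed <- stats::runif(nrow(meta)) < config$failure_rate
  growth_truth <- meta
  cmu <- mu_mult[paste0(meta$gene, ":", meta$construct_type)]
  cmu[is.na(cmu)] <- 1
  ck <- k_mult[paste0(meta$gene, ":", meta$construct_type)]
  ck[is.na(ck)] <- 1
  growth_truth$mu_true <- config$mu_wt * unname(cmu) *
    ifelse(meta$butanol == 1L, config$butanol_mu_factor, 1) *
    exp(stats::rnorm(nrow(meta), 0, config$rep_mu_cv))
  growth_truth$K_true <- config$K_wt * unname(ck) *
    ifelse(meta$butanol == 1L, 0.85, 1) *
    exp(stats::rnorm(nrow(meta), 0, config$rep_K_cv))
  growth_truth$K_true[failed] <- 0.12
  growth_truth$mu_true[failed] <- growth_truth$mu_true[failed] * 0.4

  t_min <- seq(0, config$t_hours * 60, by = config$dt_min)
  od <- matrix(0, nrow = length(t_min), ncol = nrow(meta))
  for (i in seq_len(nrow(meta))) {
    od[, i] <- simulate_growth_curve(
      growth_truth$mu_true[i], growth_truth$K_true[i], od0 = config$od0,
      t_hours = config$t_hours, dt_min = config$dt_min,
      od_cv = config$od_cv)$od
  }
  od_tbl <- dplyr::bind_cols(tibble(time_min = t_min),
                             as_tibble(stats::setNames(
                               as.data.frame(od), meta$sample_id)))

  structure(list(
    features = features,
    od = od_tbl,
    metadata = meta,
    database = db,
    truth = list(
      baseline = baseline,
      compositions = comp,
      effects = em$effects,
      marker_species = intersect(config$marker_species,
                                 names(baseline)),
      marker_drivers = em$driver,
      growth = growth_truth[, c("sample_id", "mu_true", "K_true")],
      construct_growth = construct_growth,
      failed_samples = meta$sample_id[failed],
      n_decoys = attr(features, "n_decoys")
    ),
    config = config
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$metadata), " samples, ",
      nrow(x$truth$compositions), " species, ", nrow(x$features),
      " features, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the feature table, OD table and metadata as CSV and the
#' ground-truth ledger as JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$features, file.path(dir, "features.csv"))
  readr::write_csv(study$od, file.path(dir, "od600.csv"))
  readr::write_csv(study$metadata, file.path(dir, "metadata.csv"))
  truth <- study$truth
  truth$compositions <- dplyr::bind_cols(
    tibble(species = rownames(truth$compositions)),
    as_tibble(truth$compositions))
  truth$baseline <- as.list(truth$baseline)
  truth$effects <- NULL # large; regenerate from the seed when needed
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
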