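#' @importFrom Matrix sparseMatrix colSums rowSums t Diagonal
#' @importFrom methods as
#' @importFrom stats rnbinom rbinom rlnorm rnorm runif median sd quantile
NULL

#' Default 14-cluster specification for the postnatal atlas conditions
#'
#' Cluster identifiers, relative sizes (fractions of the V1 population) and
#' clade membership. The split across clades is 40/20/12/5/15% for
#' Foxp2/Sp8/Pou6f2/MafA-Calb/Rnf220 plus an 8% cluster carrying none of the
#' clade markers (Nr5a2-high), mirroring immunohistochemical estimates of
#' the clade composition of the V1 population.
#'
#' @return data.frame with columns `cluster`, `fraction`, `clade`.
#' @export
default_cluster_spec <- function() {
  data.frame(
    cluster  = as.character(0:13),
    fraction = c(20, 9, 9, 6, 7, 9, 6, 7, 5, 8, 4, 4, 3.5, 2.5) / 100,
    clade    = c("Foxp2", "Rnf220", "Foxp2", "Pou6f2", "Foxp2", "Sp8",
                 "Rnf220", "Sp8", "MafA/Calb", "none", "Sp8", "Foxp2",
                 "Pou6f2", "Pou6f2"),
    stringsAsFactors = FALSE
  )
}

#' 11-cluster specification for the genotype-comparison conditions
#'
#' A smaller clustering with one rare Pou6f2/Nr5a2-type cluster ("10", 3% of
#' nuclei) that can be depleted in one genotype via `depletion_spec`.
#'
#' @return data.frame with columns `cluster`, `fraction`, `clade`.
#' @export
ko_cluster_spec <- function() {
  data.frame(
    cluster  = as.character(0:10),
    fraction = c(18, 13, 12, 10, 9, 8, 8, 7, 6, 6, 3) / 100,
    clade    = c("Foxp2", "Rnf220", "Foxp2", "Pou6f2", "Foxp2", "Sp8",
                 "Rnf220", "Sp8", "MafA/Calb", "none", "Pou6f2"),
    stringsAsFactors = FALSE
  )
}

#' Default clade marker planting map
#'
#' Target mean log-normalized expression of each clade marker in the clusters
#' of its clade, chosen above the per-nucleus call thresholds
#' (Foxp2 > 2.8, Sp8 > 0.8, Pou6f2 > 2.6, Chrna2 > 1.1). Calb1 mirrors
#' Chrna2 as the display proxy; Rnf220 and Nr5a2 mark their clusters at
#' levels detectable by cross-cluster z-scores.
#'
#' @param cluster_spec a cluster specification (see [default_cluster_spec()]).
#' @return data.frame with columns `gene`, `cluster`, `lognorm_mean`.
#' @export
default_clade_markers <- function(cluster_spec = default_cluster_spec()) {
  levels <- c(Foxp2 = 3.5, Sp8 = 1.5, Pou6f2 = 3.2, `MafA/Calb` = 1.8)
  genes  <- c(Foxp2 = "Foxp2", Sp8 = "Sp8", Pou6f2 = "Pou6f2",
              `MafA/Calb` = "Chrna2")
  out <- do.call(rbind, lapply(names(levels), function(cl) {
    k <- cluster_spec$cluster[cluster_spec$clade == cl]
    if (!length(k)) return(NULL)
    data.frame(gene = genes[[cl]], cluster = k, lognorm_mean = levels[[cl]])
  }))
  extra <- rbind(
    data.frame(gene = "Calb1",
               cluster = cluster_spec$cluster[cluster_spec$clade == "MafA/Calb"],
               lognorm_mean = 1.8),
    data.frame(gene = "Rnf220",
               cluster = cluster_spec$cluster[cluster_spec$clade == "Rnf220"],
               lognorm_mean = 2.5),
    data.frame(gene = "Nr5a2",
               cluster = cluster_spec$cluster[cluster_spec$clade == "none"],
               lognorm_mean = 2.0)
  )
  rbind(out, extra[extra$cluster %in% cluster_spec$cluster, ])
}

#' Default contaminant panel specification
#'
#' Non-V1 populations that survive FACS enrichment and must be removed by
#' negative selection, each defined by a marker panel and its fraction of all
#' captured nuclei (10% in total by default).
#'
#' @return named list of `list(genes, fraction)` per panel.
#' @export
default_contaminants <- function() {
  list(
    oligodendrocyte = list(genes = c("Plp1", "Mbp", "Mog", "Sox10", "Mag"),
                           fraction = 0.03),
    astrocyte       = list(genes = c("Aqp4", "Gfap", "Slc1a3", "Aldh1l1"),
                           fraction = 0.02),
    microglia       = list(genes = c("C1qa", "C1qb", "Cx3cr1", "Csf1r"),
                           fraction = 0.015),
    motor_neuron    = list(genes = c("Chat", "Isl1", "Slc5a7", "Mnx1"),
                           fraction = 0.015),
    non_v1_neuron   = list(genes = c("Vsx2", "Sox14", "Evx1", "Sim1"),
                           fraction = 0.02)
  )
}

#' Default atlas sample sheet: two replicates at four postnatal ages
#' @return data.frame with columns `sample`, `age`, `genotype`, `replicate`,
#'   `depth_scale`.
#' @export
default_samples <- function() {
  ages <- c("P0", "P14", "P28", "P56")
  data.frame(
    sample = paste0(rep(ages, each = 2), "_R", 1:2),
    age = rep(ages, each = 2),
    genotype = "WT",
    replicate = paste0("R", 1:2),
    depth_scale = 1,
    stringsAsFactors = FALSE
  )
}

#' Genotype-comparison sample sheet: Het/KO, two replicates each
#' @return data.frame as in [default_samples()].
#' @export
ko_samples <- function() {
  data.frame(
    sample = c("Het_R1", "Het_R2", "KO_R1", "KO_R2"),
    age = "P0",
    genotype = rep(c("Het", "KO"), each = 2),
    replicate = rep(paste0("R", 1:2), 2),
    depth_scale = 1,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects every parameter of the count generator. Defaults are the study
#' conditions used throughout the test suite: 20,000 nuclei, 10% contaminants
#' across five marker panels, 5% doublets, 2% ambient admixture, two
#' replicates at four ages, mean depth 2,500 UMIs, negative-binomial
#' dispersion 0.3 (0.05 for planted marker genes).
#'
#' @param n_nuclei,n_genes problem size.
#' @param cluster_spec data.frame(cluster, fraction, clade); fractions sum
#'   to 1 within the V1 population.
#' @param clade_marker_map data.frame(gene, cluster, lognorm_mean): target
#'   mean log-normalized expression of each marker in each target cluster.
#' @param contaminant_spec named list of `list(genes, fraction)`; fractions
#'   are of all nuclei and must total < 1.
#' @param ambient_fraction proportion in [0, 1) of each nucleus's counts
#'   replaced by draws from the pooled profile.
#' @param doublet_rate proportion of nuclei whose counts are sums of two
#'   nucleus profiles.
#' @param samples sample sheet (see [default_samples()]).
#' @param depletion_spec optional `list(cluster, genotype, log2fc)`: the
#'   named cluster's sampling probability is multiplied by `2^log2fc` in the
#'   named genotype.
#' @param age_effects optional data.frame(gene, age, log2fc) of planted
#'   age-specific expression shifts.
#' @param mean_depth expected UMIs per nucleus before depth scaling.
#' @param dispersion,marker_dispersion gene-level NB dispersion (1/size).
#' @param seed integer; fixes all randomness end-to-end.
#' @param profile_seed integer seed for the per-population expression
#'   profiles, separate from `seed`: two datasets drawn with different
#'   `seed` but equal `profile_seed` share their cell-type expression
#'   programs (as a query and its reference atlas would), while nucleus
#'   sampling, noise, doublets and ambient draws remain governed by `seed`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_nuclei = 20000,
                       n_genes = 2000,
                       cluster_spec = default_cluster_spec(),
                       clade_marker_map = default_clade_markers(cluster_spec),
                       contaminant_spec = default_contaminants(),
                       ambient_fraction = 0.02,
                       doublet_rate = 0.05,
                       samples = default_samples(),
                       depletion_spec = NULL,
                       age_effects = NULL,
                       mean_depth = 2500,
                       dispersion = 0.3,
                       marker_dispersion = 0.05,
                       seed = 0L,
                       profile_seed = 42L) {
  stopifnot(n_nuclei >= 1, n_genes >= 10)
  if (abs(sum(cluster_spec$fraction) - 1) > 1e-8)
    stop("cluster fractions must sum to 1")
  contam_total <- sum(vapply(contaminant_spec, `[[`, numeric(1), "fraction"))
  if (contam_total + doublet_rate >= 1 || contam_total >= 1)
    stop("contaminant fractions plus doublet rate must total < 1")
  if (ambient_fraction < 0 || ambient_fraction >= 1)
    stop("ambient_fraction must lie in [0, 1)")
  if (any(samples$depth_scale <= 0)) stop("depth scales must be positive")
  structure(list(
    n_nuclei = as.integer(n_nuclei), n_genes = as.integer(n_genes),
    cluster_spec = cluster_spec, clade_marker_map = clade_marker_map,
    contaminant_spec = contaminant_spec,
    ambient_fraction = ambient_fraction, doublet_rate = doublet_rate,
    samples = samples, depletion_spec = depletion_spec,
    age_effects = age_effects, mean_depth = mean_depth,
    dispersion = dispersion, marker_dispersion = marker_dispersion,
    seed = as.integer(seed), profile_seed = as.integer(profile_seed)
  ), class = "sim_config")
}

# Mitochondrial gene names used by the generator (mm10-style "mt-" prefix).
mito_gene_names <- function() {
  paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6", "Co3",
                  "Nd3", "Nd4l", "Nd4", "Nd5", "Nd6", "Cytb"))
}

# Full gene name vector: markers, mito, contaminant panels, filler.
sim_gene_names <- function(config) {
  special <- unique(c(
    config$clade_marker_map$gene, "Foxp2", "Sp8", "Pou6f2", "Chrna2",
    "Calb1", "Rnf220", "Nr5a2", "En1", "Nfib", "Zfhx3",
    mito_gene_names(),
    unlist(lapply(config$contaminant_spec, `[[`, "genes"),
           use.names = FALSE),
    ## panel genes always present (at background level when the matching
    ## population is absent) so panel logic is testable verbatim
    unlist(lapply(default_contaminants(), `[[`, "genes"),
           use.names = FALSE)
  ))
  if (length(special) > config$n_genes)
    stop("n_genes too small to hold the named marker genes")
  n_fill <- config$n_genes - length(special)
  c(special, sprintf("Gene%04d", seq_len(n_fill)))
}

# Convert a target mean log-normalized expression to an expected proportion
# of a nucleus's counts: v = ln(1 + 1e4 * p)  =>  p = (exp(v) - 1) / 1e4.
lognorm_to_prop <- function(v) (exp(v) - 1) / 1e4

#' Simulate a raw UMI count matrix with known ground truth
#'
#' Draws cluster-structured negative-binomial counts with planted clade
#' markers, contaminant populations carrying non-V1 marker panels, ambient
#' admixture (binomial thinning + pooled-profile replacement), doublets
#' (sums of two nucleus profiles), per-sample batch structure and an optional
#' genotype-specific depletion of one cluster.
#'
#' @param config a [sim_config()].
#' @return list of class `v1_sim` with elements `counts` (a [v1_counts]),
#'   `truth` (per-nucleus data.frame: sample, age, genotype, replicate,
#'   cluster, clade, contaminant, doublet) and `config`. `attr(truth,
#'   "composition")` holds the realized cluster x sample table.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$profile_seed)            # profiles: shared across datasets
  genes <- sim_gene_names(config)
  G <- config$n_genes
  n <- config$n_nuclei
  cs <- config$cluster_spec
  panels <- config$contaminant_spec

  ## population labels: clusters plus one pseudo-population per panel
  pops <- c(cs$cluster, names(panels))
  contam_fr <- vapply(panels, `[[`, numeric(1), "fraction")

  ## expression profiles: shared skewed baseline x per-population jitter
  base <- rlnorm(G, meanlog = 0, sdlog = 1.8)
  names(base) <- genes
  base[mito_gene_names()] <- sum(base) * 0.012 / 13  # ~1.2% mito content
  prof <- matrix(rep(base, length(pops)), nrow = G,
                 dimnames = list(genes, pops))
  jitter <- matrix(rlnorm(G * length(pops), 0, 0.6), nrow = G)
  mito <- genes %in% mito_gene_names()
  jitter[mito, ] <- 1                      # mito content equal in all pops
  prof <- prof * jitter

  ## plant clade markers: high in target clusters, fixed low background
  ## elsewhere (0.05 log-normalized units, well under every call threshold)
  csum <- colSums(prof)
  bg <- lognorm_to_prop(0.05)
  mk <- config$clade_marker_map
  for (g in unique(mk$gene)) {
    prof[g, ] <- bg * csum
    rows <- mk[mk$gene == g, ]
    prof[g, rows$cluster] <- lognorm_to_prop(rows$lognorm_mean) *
      csum[rows$cluster]
  }
  ## contaminant panel genes: same fixed background outside their own
  ## population, high (3.0 log-normalized units) inside it
  all_panel_genes <- unique(c(
    unlist(lapply(panels, `[[`, "genes"), use.names = FALSE),
    unlist(lapply(default_contaminants(), `[[`, "genes"),
           use.names = FALSE)))
  prof[all_panel_genes, ] <- bg * rep(csum, each = length(all_panel_genes))
  for (p in names(panels)) {
    pg <- panels[[p]]$genes
    prof[pg, p] <- lognorm_to_prop(3.0) * csum[p]
  }
  prof <- sweep(prof, 2, colSums(prof), "/")

  set.seed(config$seed)                    # sampling: dataset-specific
  ## nucleus-level labels
  samp <- config$samples
  sample_id <- sample(samp$sample, n, replace = TRUE)
  si <- match(sample_id, samp$sample)
  pop <- character(n)
  for (s in seq_len(nrow(samp))) {
    idx <- which(si == s)
    pv <- cs$fraction * (1 - sum(contam_fr))
    names(pv) <- cs$cluster
    dep <- config$depletion_spec
    if (!is.null(dep) && samp$genotype[s] == dep$genotype) {
      pv[dep$cluster] <- pv[dep$cluster] * 2^dep$log2fc
      pv <- pv / sum(pv) * (1 - sum(contam_fr))
    }
    pv <- c(pv, contam_fr)
    pop[idx] <- sample(pops, length(idx), replace = TRUE, prob = pv)
  }

  depth <- config$mean_depth * samp$depth_scale[si] * rlnorm(n, 0, 0.3)

  ## age-specific multipliers applied per sample block
  age_mult <- function(age) {
    m <- rep(1, G)
    ae <- config$age_effects
    if (!is.null(ae)) {
      rows <- ae[ae$age == age, ]
      m[match(rows$gene, genes)] <- 2^rows$log2fc
    }
    m
  }

  size_vec <- rep(1 / config$dispersion, G)
  size_vec[genes %in% unique(mk$gene)] <- 1 / config$marker_dispersion

  ## draw counts per (sample, population) block
  blocks <- split(seq_len(n), list(sample_id, pop), drop = TRUE)
  tri_i <- vector("list", length(blocks))
  tri_j <- vector("list", length(blocks))
  tri_x <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    s <- sample_id[idx[1]]
    p <- pop[idx[1]]
    pr <- prof[, p] * age_mult(samp$age[match(s, samp$sample)])
    pr <- pr / sum(pr)
    mu <- pr %o% depth[idx]
    x <- rnbinom(length(mu), mu = mu, size = rep(size_vec, length(idx)))
    nz <- which(x > 0L)
    tri_i[[b]] <- ((nz - 1L) %% G) + 1L
    tri_j[[b]] <- idx[((nz - 1L) %/% G) + 1L]
    tri_x[[b]] <- x[nz]
  }
  m <- Matrix::sparseMatrix(
    i = unlist(tri_i), j = unlist(tri_j), x = unlist(tri_x),
    dims = c(G, n), dimnames = list(genes, NULL)
  )

  ## doublets: add a same-sample partner's counts
  doublet <- rep(FALSE, n)
  n_dbl <- round(config$doublet_rate * n)
  if (n_dbl > 0) {
    d_idx <- sample.int(n, n_dbl)
    doublet[d_idx] <- TRUE
    partner <- vapply(d_idx, function(i) {
      pool <- which(si == si[i])
      pool <- pool[pool != i]
      if (length(pool)) pool[sample.int(length(pool), 1)] else i
    }, integer(1))
    sel <- Matrix::sparseMatrix(i = partner, j = d_idx, x = 1,
                                dims = c(n, n))
    m <- m + m %*% sel                     # add partner profile to doublets
  }

  ## ambient admixture: binomial thinning + pooled-profile replacement
  if (config$ambient_fraction > 0) {
    pooled <- Matrix::rowSums(m)
    pooled <- pooled / sum(pooled)
    before <- Matrix::colSums(m)
    m@x <- as.double(rbinom(length(m@x), m@x, 1 - config$ambient_fraction))
    m <- Matrix::drop0(m)
    removed <- as.integer(round(before - Matrix::colSums(m)))
    tot <- sum(removed)
    if (tot > 0) {
      gi <- sample.int(G, tot, replace = TRUE, prob = pooled)
      ci <- rep(seq_len(n), removed)
      add <- Matrix::sparseMatrix(i = gi, j = ci, x = 1, dims = c(G, n))
      m <- m + add
    }
  }

  barcodes <- sprintf("N%05d-%s", seq_len(n), sample_id)
  colnames(m) <- barcodes
  is_contam <- pop %in% names(panels)
  truth <- data.frame(
    barcode = barcodes,
    sample = sample_id,
    age = samp$age[si],
    genotype = samp$genotype[si],
    replicate = samp$replicate[si],
    cluster = ifelse(is_contam, NA_character_, pop),
    clade = ifelse(is_contam, NA_character_,
                   cs$clade[match(pop, cs$cluster)]),
    contaminant = ifelse(is_contam, pop, NA_character_),
    doublet = doublet,
    stringsAsFactors = FALSE
  )
  attr(truth, "composition") <-
    table(cluster = truth$cluster, sample = truth$sample)

  meta <- truth[, c("sample", "age", "genotype", "replicate")]
  structure(list(counts = v1_counts(m, meta), truth = truth,
                 config = config), class = "v1_sim")
}

#' Simulate a labelled reference expression set for positive selection
#'
#' Builds an embryonic-style reference with a "V1" class plus the non-V1
#' classes of [default_contaminants()], for exercising reference-based label
#' transfer without an external atlas. The V1 class reuses the cluster
#' structure of `config`; contaminant populations are upsampled so every
#' class is represented.
#'
#' @param n_cells reference size.
#' @param config base [sim_config()] whose profiles to reuse.
#' @param v1_fraction fraction of reference cells labelled "V1".
#' @param seed integer seed.
#' @return list with `counts` (a [v1_counts]) and `labels` (character,
#'   per cell; "V1" or a panel name).
#' @export
simulate_reference <- function(n_cells = 3000,
                               config = sim_config(),
                               v1_fraction = 0.5,
                               seed = 1L) {
  contam <- config$contaminant_spec
  scale <- (1 - v1_fraction) /
    sum(vapply(contam, `[[`, numeric(1), "fraction"))
  contam <- lapply(contam, function(p) {
    p$fraction <- p$fraction * scale
    p
  })
  ref_cfg <- sim_config(
    n_nuclei = n_cells, n_genes = config$n_genes,
    cluster_spec = config$cluster_spec,
    clade_marker_map = config$clade_marker_map,
    contaminant_spec = contam,
    ambient_fraction = 0, doublet_rate = 0,
    samples = data.frame(sample = "E13", age = "E13", genotype = "WT",
                         replicate = "R1", depth_scale = 1,
                         stringsAsFactors = FALSE),
    mean_depth = config$mean_depth, dispersion = config$dispersion,
    marker_dispersion = config$marker_dispersion, seed = seed,
    profile_seed = config$profile_seed     # shared expression programs
  )
  sim <- simulate_counts(ref_cfg)
  labels <- ifelse(is.na(sim$truth$contaminant), "V1", sim$truth$contaminant)
  list(counts = sim$counts, labels = labels)
}

#' Simulate per-neuron positions in the standardized hemisection
#'
#' Draws 2-D Gaussian-mixture positions per clade inside the standardized
#' hemisection (x in [0, 650] um lateral, y in [-400, dorsal bound] um).
#' Out-of-bounds draws are clamped to the boundary.
#'
#' @param clade_fractions named numeric vector of mixture weights per clade
#'   (normalized internally).
#' @param density_params named list (per clade) of lists with `weights`,
#'   `means` (k x 2 matrix), `sds` (k x 2 matrix).
#' @param n number of neurons.
#' @param seed integer seed.
#' @param dorsal_bound upper y limit, um.
#' @return data.frame(x, y, clade) of class `spatial_points`.
#' @export
simulate_positions <- function(clade_fractions, density_params, n,
                               seed = 0L, dorsal_bound = 500) {
  set.seed(seed)
  if (n == 0)
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                clade = character(0)),
                     class = c("spatial_points", "data.frame")))
  clade_fractions <- clade_fractions / sum(clade_fractions)
  clade <- sample(names(clade_fractions), n, replace = TRUE,
                  prob = clade_fractions)
  xy <- matrix(NA_real_, n, 2)
  for (cl in unique(clade)) {
    idx <- which(clade == cl)
    dp <- density_params[[cl]]
    if (is.null(dp)) stop("no density parameters for clade ", cl)
    comp <- sample(seq_along(dp$weights), length(idx), replace = TRUE,
                   prob = dp$weights)
    xy[idx, 1] <- rnorm(length(idx), dp$means[comp, 1], dp$sds[comp, 1])
    xy[idx, 2] <- rnorm(length(idx), dp$means[comp, 2], dp$sds[comp, 2])
  }
  xy[, 1] <- pmin(pmax(xy[, 1], 0), 650)
  xy[, 2] <- pmin(pmax(xy[, 2], -400), dorsal_bound)
  structure(data.frame(x = xy[, 1], y = xy[, 2], clade = clade),
            class = c("spatial_points", "data.frame"))
}

#' Simulate a rhythmic ventral-root trace
#'
#' A periodic bursting envelope at `freq_hz` plus broadband Gaussian noise,
#' sampled at `fs_hz` for `duration_s` seconds.
#'
#' @param freq_hz burst frequency, Hz; must be below the Nyquist limit.
#' @param fs_hz sampling rate, samples/s (study value 10000).
#' @param duration_s trace duration, s.
#' @param burst_shape "sinusoid" (pure sine) or "burst" (rectified-sine
#'   envelope raised to the 4th power, emulating discrete bursts).
#' @param noise_sd standard deviation of added white noise.
#' @param seed integer seed.
#' @return list of class `rhythm_trace` with `samples` and `fs`.
#' @export
simulate_root_trace <- function(freq_hz, fs_hz = 10000, duration_s = 60,
                                burst_shape = c("sinusoid", "burst"),
                                noise_sd = 0, seed = 0L) {
  burst_shape <- match.arg(burst_shape)
  if (freq_hz <= 0 || freq_hz >= fs_hz / 2)
    stop("freq_hz must lie in (0, fs/2)")
  set.seed(seed)
  n <- round(fs_hz * duration_s)
  t <- (seq_len(n) - 1) / fs_hz
  base <- switch(burst_shape,
    sinusoid = sin(2 * pi * freq_hz * t),
    burst = pmax(sin(2 * pi * freq_hz * t), 0)^4
  )
  x <- base + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  structure(list(samples = x, fs = fs_hz), class = "rhythm_trace")
}

# Landmark chain layout: each limb is a kinematic chain rooted at the trunk.
landmark_names <- function() {
  c("forepaw", "wrist", "elbow", "armpit",
    "hindpaw", "ankle", "knee", "groin", "anus")
}

# Rotate 2-D vector v by angle a (radians, counter-clockwise).
rot2 <- function(v, a) {
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

#' Simulate a nine-landmark tracking sequence by forward kinematics
#'
#' Places the nine tail-suspension landmarks frame by frame so that the
#' interior joint angles recomputed from the coordinates equal the planted
#' series exactly (before noise). Both limb chains are rooted at fixed trunk
#' points (armpit, groin); anus sits at a fixed offset. Angles are interior
#' angles at the named vertex in degrees.
#'
#' @param angle_series named list with numeric vectors `wrist`, `elbow`,
#'   `ankle`, `knee` (degrees, in (0, 180)), all the same length.
#' @param segment_lengths named numeric vector with positive entries
#'   `upper_arm`, `forearm`, `hand`, `thigh`, `shank`, `foot`.
#' @param noise_sd Gaussian coordinate noise, same units as segments.
#' @param seed integer seed.
#' @param fps frame rate (study value 200 frames/s), recorded as metadata.
#' @return data.frame(frame, landmark, x, y, confidence) of class
#'   `landmark_track`, with `attr(, "fps")`.
#' @export
simulate_landmarks <- function(angle_series,
                               segment_lengths = c(upper_arm = 10,
                                                   forearm = 9, hand = 4,
                                                   thigh = 12, shank = 11,
                                                   foot = 5),
                               noise_sd = 0, seed = 0L, fps = 200) {
  need <- c("wrist", "elbow", "ankle", "knee")
  if (!all(need %in% names(angle_series)))
    stop("angle_series must name wrist, elbow, ankle and knee")
  lens <- vapply(angle_series[need], length, integer(1))
  if (length(unique(lens)) != 1) stop("angle series must share a length")
  if (any(unlist(angle_series[need]) <= 0 |
          unlist(angle_series[need]) >= 180))
    stop("angles must lie strictly inside (0, 180) degrees")
  if (any(segment_lengths <= 0)) stop("segment lengths must be positive")
  set.seed(seed)
  n <- lens[1]
  L <- segment_lengths
  ## chain builder: root -> j1 -> j2 -> tip, with interior angles a1 at j1
  ## (arms to root and j2) and a2 at j2 (arms to j1 and tip).
  chain <- function(root, base_dir, l1, l2, l3, a1, a2) {
    d1 <- base_dir / sqrt(sum(base_dir^2))
    j1 <- root + l1 * d1
    d2 <- rot2(-d1, a1)             # interior angle a1 between (root-j1), (j2-j1)
    j2 <- j1 + l2 * d2
    d3 <- rot2(-d2, -a2)            # alternate bend direction
    tip <- j2 + l3 * d3
    rbind(j1, j2, tip)
  }
  deg2rad <- pi / 180
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    armpit <- c(0, 0)
    groin <- c(0, -20)
    anus <- c(0, -26)
    fore <- chain(armpit, c(1, -0.3), L["upper_arm"], L["forearm"], L["hand"],
                  angle_series$elbow[f] * deg2rad,
                  angle_series$wrist[f] * deg2rad)
    hind <- chain(groin, c(1, -0.5), L["thigh"], L["shank"], L["foot"],
                  angle_series$knee[f] * deg2rad,
                  angle_series$ankle[f] * deg2rad)
    pts <- rbind(forepaw = fore[3, ], wrist = fore[2, ], elbow = fore[1, ],
                 armpit = armpit,
                 hindpaw = hind[3, ], ankle = hind[2, ], knee = hind[1, ],
                 groin = groin, anus = anus)
    frames[[f]] <- data.frame(frame = f, landmark = rownames(pts),
                              x = pts[, 1], y = pts[, 2], confidence = 1,
                              row.names = NULL)
  }
  out <- do.call(rbind, frames)
  if (noise_sd > 0) {
    out$x <- out$x + rnorm(nrow(out), 0, noise_sd)
    out$y <- out$y + rnorm(nrow(out), 0, noise_sd)
  }
  attr(out, "fps") <- fps
  class(out) <- c("landmark_track", "data.frame")
  out
}
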