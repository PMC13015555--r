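# Seeded generators emulating every pipeline input with known ground
# truth. Each is a pure function of its spec plus seed; truth objects are
# returned separately and are never consumed by analysis operations.

#' Simulate a serology cohort
#'
#' Background-corrected ODs for a UC and a healthy-subject (HS) group.
#' Seronegative and seropositive ODs are drawn from log-normal
#' distributions (ODs are positive and right-skewed); the number of true
#' positives per group is the rounded positive fraction. Cohort sizes and
#' positive fractions default to the headline clinical cohort structure
#' (194 UC, 338 HS; 89.2% / 11.5% positive).
#'
#' @param n_uc,n_hs group sizes.
#' @param positive_fraction_uc,positive_fraction_hs fractions in [0, 1].
#' @param od_null,od_pos list(meanlog, sdlog) for seronegative and
#'   seropositive OD distributions.
#' @param isotype,antigen labels stamped on the table.
#' @param dilution serum dilution fold.
#' @param seed RNG seed.
#' @return list with `measurements` (subject_id, group, isotype, antigen,
#'   od, dilution) and `truth` (subject_id, true_positive).
#' @export
simulate_serology <- function(n_uc = 194L, n_hs = 338L,
                              positive_fraction_uc = 0.892,
                              positive_fraction_hs = 0.115,
                              od_null = list(meanlog = log(0.08), sdlog = 0.5),
                              od_pos = list(meanlog = log(0.9), sdlog = 0.6),
                              isotype = "IgG", antigen = "avb6_human",
                              dilution = 100, seed = 1L) {
  stopifnot(positive_fraction_uc >= 0, positive_fraction_uc <= 1,
            positive_fraction_hs >= 0, positive_fraction_hs <= 1,
            od_null$sdlog > 0, od_pos$sdlog > 0)
  with_seed(seed, {
    k_uc <- round(n_uc * positive_fraction_uc)
    k_hs <- round(n_hs * positive_fraction_hs)
    draw <- function(n, k) {
      truth <- c(rep(TRUE, k), rep(FALSE, n - k))
      od <- numeric(n)
      od[truth] <- stats::rlnorm(k, od_pos$meanlog, od_pos$sdlog)
      od[!truth] <- stats::rlnorm(n - k, od_null$meanlog, od_null$sdlog)
      list(od = od, truth = truth)
    }
    uc <- draw(n_uc, k_uc)
    hs <- draw(n_hs, k_hs)
    ids <- c(sprintf("UC%03d", seq_len(n_uc)), sprintf("HS%03d", seq_len(n_hs)))
    list(
      measurements = data.frame(
        subject_id = ids,
        group = c(rep("UC", n_uc), rep("HS", n_hs)),
        isotype = isotype, antigen = antigen,
        od = c(uc$od, hs$od), dilution = dilution,
        stringsAsFactors = FALSE),
      truth = data.frame(subject_id = ids,
                         true_positive = c(uc$truth, hs$truth),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate an adhesion-blocking assay plate
#'
#' One plate of serum wells plus untreated controls. HS sera and
#' non-inhibitory samples adhere at the untreated level; planted
#' inhibitors adhere at `adherence_ratio` of it. Replicate noise is
#' normal with coefficient of variation `replicate_cv` (counts truncated
#' at 0). Defaults mirror the blocking-assay cohort scale (29 test sera,
#' 10 true inhibitors, triplicate wells).
#'
#' @param n_samples number of test serum samples.
#' @param n_true_inhibitors planted inhibitors among them.
#' @param adherence_ratio inhibitor adherence as a fraction of control.
#' @param replicate_cv replicate coefficient of variation.
#' @param replicates_per_arm wells per serum sample.
#' @param n_hs number of HS control sera.
#' @param baseline_count mean adherent count of untreated wells.
#' @param seed RNG seed.
#' @return list with `plate` (plate_id, well_id, condition, sample_id,
#'   adherent), `hs_samples`, and `truth` (sample_id, true_inhibitor).
#' @export
simulate_adhesion <- function(n_samples = 29L, n_true_inhibitors = 10L,
                              adherence_ratio = 0.5, replicate_cv = 0.1,
                              replicates_per_arm = 3L, n_hs = 5L,
                              baseline_count = 1000, seed = 1L) {
  stopifnot(n_true_inhibitors <= n_samples, replicate_cv >= 0,
            adherence_ratio > 0, adherence_ratio <= 1,
            replicates_per_arm >= 2L, n_hs >= 1L)
  with_seed(seed, {
    noisy <- function(mu, n) pmax(stats::rnorm(n, mu, replicate_cv * mu), 0)
    wells <- list(data.frame(
      condition = "untreated", sample_id = NA_character_,
      adherent = noisy(baseline_count, max(2L, replicates_per_arm)),
      stringsAsFactors = FALSE))
    hs_ids <- sprintf("HS%02d", seq_len(n_hs))
    for (id in hs_ids) {
      wells[[length(wells) + 1L]] <- data.frame(
        condition = "serum", sample_id = id,
        adherent = noisy(baseline_count, replicates_per_arm),
        stringsAsFactors = FALSE)
    }
    uc_ids <- sprintf("UC%02d", seq_len(n_samples))
    inhib <- c(rep(TRUE, n_true_inhibitors),
               rep(FALSE, n_samples - n_true_inhibitors))
    for (i in seq_len(n_samples)) {
      mu <- baseline_count * if (inhib[i]) adherence_ratio else 1
      wells[[length(wells) + 1L]] <- data.frame(
        condition = "serum", sample_id = uc_ids[i],
        adherent = noisy(mu, replicates_per_arm),
        stringsAsFactors = FALSE)
    }
    plate <- do.call(rbind, wells)
    plate <- cbind(plate_id = "P1",
                   well_id = sprintf("W%03d", seq_len(nrow(plate))), plate)
    list(plate = plate, hs_samples = hs_ids,
         truth = data.frame(sample_id = uc_ids, true_inhibitor = inhib,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a TGF-beta reporter assay
#'
#' Reporter OD620 per sample well; treated samples reduce reporter
#' activity by `reduction` relative to the HS control mean.
#'
#' @param n_hs,n_uc sample counts.
#' @param reduction fractional reduction of reporter activity in UC
#'   samples (0.4 = 40% reduction).
#' @param baseline_od mean HS reporter OD620.
#' @param cv replicate coefficient of variation.
#' @param replicates wells per sample.
#' @param seed RNG seed.
#' @return list with `reporter` (sample_id, od620) and `hs_samples`.
#' @export
simulate_reporter <- function(n_hs = 5L, n_uc = 10L, reduction = 0.4,
                              baseline_od = 1.0, cv = 0.05,
                              replicates = 3L, seed = 1L) {
  stopifnot(reduction >= 0, reduction < 1, cv >= 0)
  with_seed(seed, {
    ids <- c(sprintf("HS%02d", seq_len(n_hs)), sprintf("UC%02d", seq_len(n_uc)))
    mu <- c(rep(baseline_od, n_hs), rep(baseline_od * (1 - reduction), n_uc))
    reporter <- data.frame(
      sample_id = rep(ids, each = replicates),
      od620 = pmax(stats::rnorm(length(ids) * replicates,
                                rep(mu, each = replicates),
                                cv * rep(mu, each = replicates)), 0),
      stringsAsFactors = FALSE)
    list(reporter = reporter, hs_samples = ids[seq_len(n_hs)])
  })
}

#' Simulate a treatment-structured expression matrix with marker sets
#'
#' Log2-scale expression with per-gene baselines, i.i.d. normal noise,
#' and planted treatment effects on lineage marker genes, in SD units of
#' the noise. Default effects reproduce the observed direction pattern:
#' exogenous TGF-beta suppresses goblet and absorptive programs while
#' alpha-v-beta-6 blockade induces them, with stem programs moving
#' oppositely.
#'
#' @param n_genes total genes.
#' @param samples_per_arm samples per treatment arm.
#' @param treatments treatment arms (first is the reference).
#' @param effects named list: per treatment, a named numeric vector of
#'   effect sizes (in noise-SD units) per marker set.
#' @param set_size marker genes per set.
#' @param noise_sd residual SD on the log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param seed RNG seed.
#' @return list with `mat` (genes x samples), `gene_sets` (named list),
#'   `samples` (sample, treatment), and `effects` (the truth).
#' @export
simulate_expression <- function(n_genes = 2000L, samples_per_arm = 3L,
                                treatments = c("untreated", "anti_avb6",
                                               "anti_tgfb", "tgfb"),
                                effects = list(
                                  anti_avb6 = c(goblet = 1, absorptive = 1,
                                                stem = -1),
                                  anti_tgfb = c(goblet = 0.5,
                                                absorptive = 0.5,
                                                stem = -0.5),
                                  tgfb = c(goblet = -1, absorptive = -1,
                                           stem = 1)),
                                set_size = 30L, noise_sd = 1,
                                baseline_mean = 5, baseline_sd = 1.5,
                                seed = 1L) {
  stopifnot(samples_per_arm >= 2L, noise_sd > 0,
            all(vapply(effects, function(e) all(is.finite(e)), logical(1))))
  subsets <- unique(unlist(lapply(effects, names)))
  stopifnot(n_genes >= length(subsets) * set_size)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    gene_sets <- list()
    for (i in seq_along(subsets)) {
      gene_sets[[subsets[i]]] <-
        genes[((i - 1L) * set_size + 1L):(i * set_size)]
    }
    samples <- data.frame(
      sample = paste0(rep(treatments, each = samples_per_arm), "_",
                      rep(seq_len(samples_per_arm), length(treatments))),
      treatment = rep(treatments, each = samples_per_arm),
      stringsAsFactors = FALSE)
    n_s <- nrow(samples)
    base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    mat <- matrix(base, n_genes, n_s) +
      matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), n_genes, n_s)
    dimnames(mat) <- list(genes, samples$sample)
    for (tr in names(effects)) {
      cols <- which(samples$treatment == tr)
      if (length(cols) == 0L) next
      for (ss in names(effects[[tr]])) {
        rows <- match(gene_sets[[ss]], genes)
        mat[rows, cols] <- mat[rows, cols] + effects[[tr]][[ss]] * noise_sd
      }
    }
    list(mat = mat, gene_sets = gene_sets, samples = samples,
         effects = effects)
  })
}

# Default spatial cluster layout: per-cluster colon-length (s) range,
# crypt-lumen (d) range and density weight. Weights sum to 1; densities
# are uniform over each cluster's s-range. Smooth muscle hugs the serosal
# side (d ~ 0), intercrypt goblet cells the luminal surface of the distal
# colon, and one canonical goblet cluster is confined to the mid colon
# (the cluster expanded in the knockout genotype).
default_spatial_layout <- function() {
  data.frame(
    cluster = c("smooth_muscle", "intercrypt_gc", "enterocyte_proximal",
                "enterocyte_distal", "gc_proliferating", "gc_canonical_mid",
                "gc_noncanonical"),
    s_lo = c(0, 0.55, 0, 0.55, 0, 0.34, 0),
    s_hi = c(1, 1, 0.45, 1, 1, 0.66, 1),
    d_lo = c(0, 0.92, 0.3, 0.3, 0.05, 0.15, 0.35),
    d_hi = c(0.05, 1, 1, 1, 0.4, 0.75, 0.95),
    weight = c(0.10, 0.06, 0.22, 0.20, 0.17, 0.012, 0.238),
    stringsAsFactors = FALSE
  )
}

# Marker-gene Poisson rates per cluster for the sparse counts table.
default_marker_rates <- function(clusters) {
  rate <- function(high_in, hi = 4, lo = 0.05) {
    stats::setNames(ifelse(clusters %in% high_in, hi, lo), clusters)
  }
  list(Retnlb = rate("gc_canonical_mid"),
       Aqp8 = rate("intercrypt_gc"),
       Muc2 = rate(c("gc_proliferating", "gc_canonical_mid",
                     "gc_noncanonical", "intercrypt_gc"), hi = 6, lo = 0.1),
       Car8 = rate(c("gc_canonical_mid", "gc_noncanonical"), hi = 2))
}

#' Simulate a two-genotype swiss-roll spatial dataset
#'
#' Cells are placed at true (s, d) positions according to a cluster
#' layout (uniform within each cluster's s- and d-range, counts Poisson
#' around the density weights), with designated clusters expanded by a
#' multiplicative density factor in the mid s-range for the knockout
#' genotype. True positions are then rolled onto an Archimedean spiral:
#' theta from the closed-form inverse arc length (distal end innermost),
#' radius offset from the centerline by the crypt-lumen depth (luminal
#' side inward), plus Gaussian radial and small uniform angular jitter.
#'
#' @param colon_length colon length in um.
#' @param a,b spiral parameters (um, um/rad); the angular extent is
#'   derived so the spiral arc length equals `colon_length`, or taken
#'   from `theta_end` if given (error if its arc is too short).
#' @param half_thickness tissue half-thickness in um.
#' @param cells_per_mm cell density per genotype per mm of colon.
#' @param layout cluster layout data.frame (see
#'   [default_spatial_layout()]).
#' @param knockout_expansion density multiplier applied to
#'   `expanded_clusters` within the mid s-range in the knockout.
#' @param expanded_clusters clusters subject to the expansion.
#' @param mid_range the s-interval where the expansion applies.
#' @param jitter_r Gaussian radial jitter SD (um).
#' @param jitter_theta half-width of uniform angular jitter (rad).
#' @param center spiral center per sample (list of xy per genotype or a
#'   single xy used for both).
#' @param theta_end optional explicit angular extent.
#' @param seed RNG seed.
#' @return list with `cells` (cell_id, sample_id, genotype, x, y,
#'   cluster), `truth` (cell_id, s, d, region, cluster), `counts`
#'   (sparse cell_id/gene/count triplets for marker genes), and
#'   `spiral_truth` (a, b, per-sample centers, theta_end,
#'   half_thickness).
#' @export
simulate_swiss_roll <- function(colon_length = 60000, a = 800, b = 120,
                                half_thickness = 250, cells_per_mm = 200,
                                layout = default_spatial_layout(),
                                knockout_expansion = 2,
                                expanded_clusters = "gc_canonical_mid",
                                mid_range = c(1 / 3, 2 / 3),
                                jitter_r = 20, jitter_theta = 0.005,
                                center = c(1000, 800), theta_end = NULL,
                                seed = 1L) {
  stopifnot(b > 0, half_thickness > 0, all(layout$weight >= 0),
            all(layout$s_lo >= 0), all(layout$s_hi <= 1),
            all(layout$d_lo >= 0), all(layout$d_hi <= 1),
            knockout_expansion >= 0)
  # angular extent: the spiral's true arc length must equal the colon
  # length (closed-form Archimedean arc length, not the polar area)
  arc0 <- function(theta) arc_length(list(a = a, b = b), theta,
                                     theta_from = 0)
  if (is.null(theta_end)) {
    upper <- (-a + sqrt(a^2 + 2 * b * colon_length)) / b + 2 * pi
    theta_end <- stats::uniroot(function(t) arc0(t) - colon_length,
                                c(1e-6, upper), tol = 1e-10)$root
  } else if (arc0(theta_end) < colon_length) {
    stop("spiral arc length is shorter than colon_length")
  }
  if (theta_end < 2 * pi) stop("spiral must cover at least one full turn")
  sp_truth <- spiral_model(center = center, a = a, b = b,
                           theta_range = c(0, theta_end),
                           half_thickness = half_thickness,
                           luminal = "inner", distal = "inner")
  n_per_genotype <- cells_per_mm * colon_length / 1000
  with_seed(seed, {
    place_genotype <- function(genotype, sample_id, cen) {
      segs <- list()
      for (i in seq_len(nrow(layout))) {
        row <- layout[i, ]
        len <- row$s_hi - row$s_lo
        # split the cluster's s-range at the mid-colon interval so the
        # knockout expansion can scale density inside it only
        cuts <- sort(unique(c(row$s_lo, row$s_hi,
                              pmin(pmax(mid_range, row$s_lo), row$s_hi))))
        for (j in seq_len(length(cuts) - 1L)) {
          lo <- cuts[j]; hi <- cuts[j + 1L]
          if (hi <= lo) next
          mult <- 1
          if (genotype == "knockout" && row$cluster %in% expanded_clusters &&
              lo >= mid_range[1] - 1e-12 && hi <= mid_range[2] + 1e-12) {
            mult <- knockout_expansion
          }
          lam <- n_per_genotype * row$weight * (hi - lo) / len * mult
          n <- stats::rpois(1L, lam)
          if (n == 0L) next
          segs[[length(segs) + 1L]] <- data.frame(
            cluster = row$cluster,
            s = stats::runif(n, lo, hi),
            d = stats::runif(n, row$d_lo, row$d_hi),
            stringsAsFactors = FALSE)
        }
      }
      pts <- do.call(rbind, segs)
      n <- nrow(pts)
      # roll (s, d) onto the spiral: distal (s = 1) at the inner terminus
      L_target <- (1 - pts$s) * colon_length
      theta <- invert_arc_length(sp_truth, L_target) +
        stats::runif(n, -jitter_theta, jitter_theta)
      radius <- a + b * theta - (pts$d - 0.5) * 2 * half_thickness +
        stats::rnorm(n, 0, jitter_r)
      ang <- if (sp_truth$flip) -theta else theta
      data.frame(
        cell_id = paste0(sample_id, "_c", seq_len(n)),
        sample_id = sample_id, genotype = genotype,
        x = cen[1] + radius * cos(ang), y = cen[2] + radius * sin(ang),
        cluster = pts$cluster, s = pts$s, d = pts$d,
        stringsAsFactors = FALSE)
    }
    centers <- if (is.list(center)) center else
      list(control = center, knockout = center + c(12000, 0))
    ctrl <- place_genotype("control", "ctrl_1", centers$control)
    ko <- place_genotype("knockout", "ko_1", centers$knockout)
    all_cells <- rbind(ctrl, ko)
    truth <- data.frame(cell_id = all_cells$cell_id, s = all_cells$s,
                        d = all_cells$d,
                        region = assign_regions(all_cells$s),
                        cluster = all_cells$cluster,
                        stringsAsFactors = FALSE)
    cells <- all_cells[, c("cell_id", "sample_id", "genotype", "x", "y",
                           "cluster")]
    # sparse marker counts: Poisson per cell with cluster-specific rates
    rates <- default_marker_rates(unique(layout$cluster))
    triplets <- list()
    for (g in names(rates)) {
      lam <- rates[[g]][cells$cluster]
      cnt <- stats::rpois(nrow(cells), lam)
      keep <- cnt > 0L
      triplets[[g]] <- data.frame(cell_id = cells$cell_id[keep], gene = g,
                                  count = cnt[keep], stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, triplets)
    rownames(counts) <- NULL
    list(cells = cells, truth = truth, counts = counts,
         spiral_truth = list(a = a, b = b, centers = centers,
                             theta_end = theta_end,
                             half_thickness = half_thickness))
  })
}

#' Simulate a monoclonal standard curve table
#'
#' Forward-4PL ODs at the given standard concentrations, with optional
#' Gaussian noise, replicated.
#'
#' @param params list(lower, upper, ec50, hill) of the true 4PL.
#' @param concentrations standard concentrations (> 0).
#' @param noise_sd OD noise SD.
#' @param replicates replicate wells per concentration.
#' @param seed RNG seed.
#' @return list with `standards` (concentration, od, replicate) and
#'   `truth` (the params).
#' @export
simulate_standard_curve <- function(params = list(lower = 0.05, upper = 3,
                                                  ec50 = 100, hill = 1),
                                    concentrations = c(1, 10, 100, 1000,
                                                       10000),
                                    noise_sd = 0, replicates = 2L,
                                    seed = 1L) {
  stopifnot(all(concentrations > 0), noise_sd >= 0, replicates >= 1L)
  with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    od <- fpl_forward(conc, params) +
      stats::rnorm(length(conc), 0, noise_sd)
    list(standards = data.frame(concentration = conc, od = od,
                                replicate = rep(seq_len(replicates),
                                                times = length(concentrations)),
                                stringsAsFactors = FALSE),
         truth = params)
  })
}
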