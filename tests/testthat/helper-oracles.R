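# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain nested-loop enumeration for the screen,
# deSolve integration for the gating model, a lattice search for the
# activation fit, and a permutation test for the ANOVA.

# --- brute-force screen ------------------------------------------------

count_alt <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  a <- strsplit(gt, "[/|]")[[1]]
  if (any(a == ".")) return(NA_integer_)
  sum(a == "1")
}

# Straight re-derivation of the recessive call set from the cohort
# matrices: every (variant, affected child) pair, then every variant pair
# per (proband, gene). Returns a data.frame of rows
# (variant_id, proband_id, model) with compound-het pairs expanded.
brute_force_recessive <- function(cohort, config = cohort$config) {
  v <- cohort$variants; ped <- cohort$pedigree
  children <- ped[ped$affected == "yes", ]
  rows <- list()
  per_gene_het <- list()

  for (i in seq_len(nrow(v))) {
    if (!v$gene[i] %in% config$gene_panel) next
    maf <- suppressWarnings(max(c(0, cohort$mafs[i, ]), na.rm = TRUE))
    if (maf > config$maf_rare) next
    dmg <- v$consequence[i] %in% c("stop_gain", "stop_loss", "frameshift",
                                   "splice") ||
      (v$consequence[i] == "missense" && !is.na(v$cadd[i]) &&
         v$cadd[i] >= config$cadd_min)
    if (!dmg) next
    on_x <- v$chrom[i] %in% c("X", "chrX") &&
      !((v$pos[i] >= 10001 && v$pos[i] <= 2781479) ||
          (v$pos[i] >= 155701383 && v$pos[i] <= 156030895))

    good <- function(s) {
      s %in% colnames(cohort$gt) &&
        !is.na(cohort$dp[i, s]) && !is.na(cohort$gq[i, s]) &&
        cohort$dp[i, s] >= config$dp_min && cohort$gq[i, s] >= config$gq_min
    }
    nalt <- function(s) {
      if (!good(s)) return(NA_integer_)
      count_alt(cohort$gt[i, s])
    }

    for (ci in seq_len(nrow(children))) {
      ch <- children[ci, ]
      ca <- nalt(ch$sample_id)
      if (is.na(ca) || ca == 0) next
      fa <- nalt(ch$father_id); mo <- nalt(ch$mother_id)
      ploidy <- length(strsplit(cohort$gt[i, ch$sample_id], "[/|]")[[1]])
      if (on_x && ch$sex == "M") {
        if (identical(fa, 0L) && identical(mo, 0L)) next  # de novo
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = v$variant_id[i], proband_id = ch$sample_id,
          model = "hemizygous", stringsAsFactors = FALSE)
      } else if (ploidy >= 2 && ca >= 2) {
        if (identical(fa, 0L) || identical(mo, 0L)) next  # mendel error
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = v$variant_id[i], proband_id = ch$sample_id,
          model = "homozygous", stringsAsFactors = FALSE)
      } else if (ca == 1) {
        origin <- if (!is.na(mo) && mo > 0 && (!is.na(fa) && fa == 0)) {
          "maternal"
        } else if (!is.na(fa) && fa > 0 && (!is.na(mo) && mo == 0)) {
          "paternal"
        } else NA_character_
        if (!is.na(origin)) {
          per_gene_het[[length(per_gene_het) + 1L]] <- data.frame(
            variant_id = v$variant_id[i], proband_id = ch$sample_id,
            gene = v$gene[i], origin = origin,
            father_id = ch$father_id, mother_id = ch$mother_id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  het <- if (length(per_gene_het)) do.call(rbind, per_gene_het) else NULL
  if (!is.null(het)) {
    for (pb in unique(het$proband_id)) {
      for (g in unique(het$gene[het$proband_id == pb])) {
        grp <- het[het$proband_id == pb & het$gene == g, ]
        if (nrow(grp) < 2) next
        for (a in seq_len(nrow(grp) - 1)) {
          for (b in (a + 1):nrow(grp)) {
            if (grp$origin[a] == grp$origin[b]) next
            # cis check: one parent carrying both
            cis <- FALSE
            for (par in c(grp$father_id[a], grp$mother_id[a])) {
              if (par == "0" || !par %in% colnames(cohort$gt)) next
              na <- count_alt(cohort$gt[grp$variant_id[a], par])
              nb <- count_alt(cohort$gt[grp$variant_id[b], par])
              if (!is.na(na) && na > 0 && !is.na(nb) && nb > 0) cis <- TRUE
            }
            if (cis) next
            for (vv in c(grp$variant_id[a], grp$variant_id[b])) {
              rows[[length(rows) + 1L]] <- data.frame(
                variant_id = vv, proband_id = pb, model = "compound_het",
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(variant_id = character(0), proband_id = character(0),
                      model = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

# --- random cohort generator for property tests ------------------------

random_cohort_files <- function(dir, n_variants = 20, seed = 1) {
  set.seed(seed)
  ped <- data.frame(
    family_id = c(rep("F1", 3), rep("F2", 4), rep("F3", 3)),
    sample_id = c("F1.1", "F1.2", "F1.3",
                  "F2.1", "F2.2", "F2.3", "F2.4",
                  "F3.1", "F3.2", "F3.3"),
    father_id = c("0", "0", "F1.1", "0", "0", "F2.1", "F2.1",
                  "0", "0", "F3.1"),
    mother_id = c("0", "0", "F1.2", "0", "0", "F2.2", "F2.2",
                  "0", "0", "F3.2"),
    sex_code = c("1", "2", sample(c("1", "2"), 1), "1", "2",
                 sample(c("1", "2"), 1), "2", "1", "2", "1"),
    phen_code = c("1", "1", "2", "1", "1", "2", "1", "1", "1", "2"),
    stringsAsFactors = FALSE)
  samples <- ped$sample_id
  sex <- setNames(ped$sex_code, samples)

  genes <- c(sample(vgcc_panel(), 5), "NOTPANEL1")
  csqs <- c("missense", "synonymous", "stop_gain", "frameshift", "other")
  variants <- data.frame(
    chrom = sample(c("chr1", "chr16", "chrX"), n_variants, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2)),
    pos = sample(3e6:5e7, n_variants),
    rsid = ".",
    ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
    alt = NA_character_,
    gene = sample(genes, n_variants, replace = TRUE),
    consequence = sample(csqs, n_variants, replace = TRUE,
                         prob = c(0.5, 0.2, 0.1, 0.1, 0.1)),
    cadd = round(runif(n_variants, 0, 35), 2),
    af_v3 = signif(10^runif(n_variants, -6, -0.7), 3),
    af_v2 = NA_real_,
    stringsAsFactors = FALSE)
  variants$alt <- vapply(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  has_v2 <- runif(n_variants) < 0.5
  variants$af_v2[has_v2] <- signif(10^runif(sum(has_v2), -6, -0.7), 3)
  # occasional missing CADD
  variants$cadd[runif(n_variants) < 0.1] <- NA_real_

  gt <- matrix("0/0", n_variants, length(samples),
               dimnames = list(NULL, samples))
  dp <- matrix(sample(5:60, n_variants * length(samples), replace = TRUE),
               n_variants, length(samples), dimnames = list(NULL, samples))
  gq <- matrix(sample(10:99, n_variants * length(samples), replace = TRUE),
               n_variants, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n_variants)) {
    hap_x <- variants$chrom[i] == "chrX"
    for (s in samples) {
      male_hap <- hap_x && sex[[s]] == "1"
      r <- runif(1)
      g <- if (r < 0.6) "ref" else if (r < 0.92) "het" else "hom"
      gt[i, s] <- if (male_hap) {
        if (g == "ref") "0" else "1"
      } else {
        c(ref = "0/0", het = "0/1", hom = "1/1")[[g]]
      }
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "random.vcf")
  pedf <- file.path(dir, "random.ped")
  write_cohort_vcf(variants, gt, dp, gq, vcf)
  write.table(ped, pedf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(vcf = vcf, ped = pedf)
}

# --- fine-step ODE oracle for the gating model --------------------------

ode_peak_oracle <- function(params, v_test, capacitance, t_ms = 100,
                            dt = 0.002) {
  m0 <- m_inf(params, -120); h0 <- h_inf(params, -120)
  deriv <- function(t, y, p) {
    list(c((m_inf(params, v_test) - y[1]) / tau_m(params, v_test),
           (h_inf(params, v_test) - y[2]) / tau_h(params, v_test)))
  }
  times <- seq(0, t_ms, by = dt)
  sol <- deSolve::lsoda(c(m = m0, h = h0), times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  i_pa <- capacitance * params$gmax_density * sol[, "m"] * sol[, "h"] *
    (v_test - params$erev)
  list(peak_pa = min(i_pa), t_peak_ms = times[which.min(i_pa)],
       trace = data.frame(t_ms = times, i_pa = i_pa))
}

# --- lattice-search oracle for the activation fit -----------------------

grid_fit_rss <- function(iv, erev_grid = seq(20, 40, by = 1),
                         vh_grid = seq(-60, -30, by = 0.25),
                         s_grid = seq(3, 8, by = 0.1)) {
  v <- iv$v_mv; y <- iv$density_pa_pf
  best <- Inf
  for (erev in erev_grid) {
    for (s in s_grid) {
      for (vh in vh_grid) {
        b <- (v - erev) / (1 + exp((vh - v) / s))
        gmax <- sum(b * y) / sum(b * b)
        rss <- sum((y - gmax * b)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# --- permutation one-way ANOVA -----------------------------------------

perm_anova_p <- function(values, group, n_perm = 2000, seed = 7) {
  set.seed(seed)
  f_stat <- function(vals) {
    g <- factor(group)
    grand <- mean(vals)
    means <- tapply(vals, g, mean)
    sizes <- table(g)
    ssb <- sum(sizes * (means - grand)^2) / (nlevels(g) - 1)
    ssw <- sum((vals - means[g])^2) / (length(vals) - nlevels(g))
    ssb / ssw
  }
  f0 <- f_stat(values)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(sample(values)) >= f0) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
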