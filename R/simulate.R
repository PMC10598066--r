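# Synthetic-data generators with planted ground truth. Each generator is a
# pure function of (spec, seed): the global RNG state is saved and restored.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Specification of a synthetic two-strain expression experiment
#'
#' Defaults emulate the structure of the study design the pipeline targets:
#' three timepoints (4, 8, 10 weeks), three case replicates and one control
#' replicate per timepoint, log-normal baseline signals with multiplicative
#' log-normal replicate noise, and four planted gene classes. Planted fold
#' changes (2-fold up, 3-fold down) sit well beyond the screen thresholds
#' (1.5 / 2.25) relative to the default replicate noise, so recovery of the
#' planted classes is the designed behaviour, not a tuning outcome. Baselines
#' of planted non-null genes are truncated above twice the detection floor so
#' that a planted gene can never be lost to the low-signal filter.
#'
#' @param n_genes Total genes. Default 2000.
#' @param timepoints Sampling weeks. Default `c(4, 8, 10)`.
#' @param case_replicates,control_replicates Replicates per timepoint.
#'   Defaults 3 and 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (natural log). Defaults `log(100)` and 1.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   (natural-log scale). Default 0.05.
#' @param n_case_only_up,n_shared_up,n_case_only_down Planted class sizes.
#'   Defaults 20 each.
#' @param fold_up,fold_shared,fold_down Planted effect sizes (ratios > 1).
#'   Defaults 2, 2 and 3.
#' @param signal_floor Detection floor used to truncate planted baselines.
#'   Default 5.
#' @param seed Integer seed. Default 0.
#' @return A list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 2000,
                                timepoints = c(4, 8, 10),
                                case_replicates = 3,
                                control_replicates = 1,
                                baseline_meanlog = log(100),
                                baseline_sdlog = 1,
                                noise_sd = 0.05,
                                n_case_only_up = 20,
                                n_shared_up = 20,
                                n_case_only_down = 20,
                                fold_up = 2,
                                fold_shared = 2,
                                fold_down = 3,
                                signal_floor = 5,
                                seed = 0L) {
  n_planted <- n_case_only_up + n_shared_up + n_case_only_down
  if (n_planted > n_genes) {
    stop("planted class counts exceed n_genes")
  }
  stopifnot(fold_up > 1, fold_shared > 1, fold_down > 1, noise_sd >= 0)
  structure(as.list(environment())[names(formals(expression_sim_spec))],
            class = "expression_sim_spec")
}

#' Simulate a two-strain expression experiment with planted truth
#'
#' Baseline signals are log-normal; planted effects multiply the 8- and
#' 10-week group means: `case_only_up` and `case_only_down` genes change in
#' the case strain only, `shared_up` genes change identically in both
#' strains (maturation signal), remaining genes are null. Multiplicative
#' log-normal noise is applied per sample.
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `case` and `control` [expr_matrix()] objects and
#'   `truth`, a `data.frame` of `gene` and `class`
#'   (`case_only_up` / `shared_up` / `case_only_down` / `null`).
#' @export
simulate_expression <- function(spec = expression_sim_spec()) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  local_seed(spec$seed, {
    genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
    classes <- rep("null", spec$n_genes)
    idx <- seq_len(spec$n_case_only_up + spec$n_shared_up + spec$n_case_only_down)
    classes[idx] <- rep(c("case_only_up", "shared_up", "case_only_down"),
                        c(spec$n_case_only_up, spec$n_shared_up,
                          spec$n_case_only_down))
    baseline <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog,
                              spec$baseline_sdlog)
    planted <- classes != "null"
    # planted genes must be detectable: resample baselines below 2x floor
    low <- planted & baseline < 2 * spec$signal_floor
    while (any(low)) {
      baseline[low] <- stats::rlnorm(sum(low), spec$baseline_meanlog,
                                     spec$baseline_sdlog)
      low <- planted & baseline < 2 * spec$signal_floor
    }

    effect <- function(strain, tp) {
      e <- rep(1, spec$n_genes)
      if (tp == spec$timepoints[1L]) return(e)
      if (strain == "case") {
        e[classes == "case_only_up"] <- spec$fold_up
        e[classes == "case_only_down"] <- 1 / spec$fold_down
      }
      e[classes == "shared_up"] <- spec$fold_shared
      e
    }
    build <- function(strain, n_rep) {
      cols <- list(); meta <- list()
      for (tp in spec$timepoints) {
        mu <- baseline * effect(strain, tp)
        for (r in seq_len(n_rep)) {
          noise <- exp(stats::rnorm(spec$n_genes, 0, spec$noise_sd))
          cols[[length(cols) + 1L]] <- mu * noise
          meta[[length(meta) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%dwk_%d", strain, tp, r),
            strain = strain, timepoint = tp, replicate = r,
            stringsAsFactors = FALSE)
        }
      }
      sig <- do.call(cbind, cols)
      rownames(sig) <- genes
      samples <- do.call(rbind, meta)
      colnames(sig) <- samples$sample_id
      expr_matrix(sig, samples)
    }
    list(case = build("case", spec$case_replicates),
         control = build("control", spec$control_replicates),
         truth = data.frame(gene = genes, class = classes,
                            stringsAsFactors = FALSE))
  })
}

#' Specification of a synthetic paired-assembly variant experiment
#'
#' Defaults plant one homozygous moderate-impact causal variant inside a
#' target locus, plus decoys engineered to die at exactly one funnel stage
#' each, background variants outside the locus, and a panel of non-affected
#' strains. The two assemblies are related by a uniform per-chromosome
#' coordinate shift — deliberately the colinearity model assumed by
#' [estimate_marker_position()], so estimator exactness is testable.
#'
#' @param chrom_lengths Named vector of chromosome lengths. Default two
#'   rat-sized chromosomes.
#' @param causal_locus Target [locus_interval()] containing the causal
#'   variant.
#' @param n_background Background variants outside the locus. Default 500.
#' @param n_decoys_per_mode In-scope decoys per failure mode (`het`,
#'   `panel_shared`, `single_assembly_only`, `off_locus`, `low_impact`).
#'   Default 5.
#' @param assembly_shift Named per-chromosome coordinate offset of assembly
#'   B relative to assembly A; `NULL` (default) draws one uniformly from
#'   -50000..50000 per chromosome.
#' @param n_panel_strains Non-affected strains in the panel. Default 10.
#' @param n_panel_private Private variants per panel strain. Default 50.
#' @param assembly_a,assembly_b Assembly labels.
#' @param seed Integer seed. Default 0.
#' @return A list of class `variant_sim_spec`.
#' @export
variant_sim_spec <- function(chrom_lengths = c(chr8 = 130e6, chr15 = 110e6),
                             causal_locus = locus_interval("target", "chr8",
                                                           40e6, 60e6),
                             n_background = 500,
                             n_decoys_per_mode = 5,
                             assembly_shift = NULL,
                             n_panel_strains = 10,
                             n_panel_private = 50,
                             assembly_a = "asmA",
                             assembly_b = "asmB",
                             seed = 0L) {
  if (!causal_locus$chrom %in% names(chrom_lengths)) {
    stop("causal locus chromosome not in chrom_lengths")
  }
  if (causal_locus$end > chrom_lengths[[causal_locus$chrom]]) {
    stop("causal locus extends beyond its chromosome")
  }
  structure(as.list(environment())[names(formals(variant_sim_spec))],
            class = "variant_sim_spec")
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate paired-assembly case call sets, a strain panel and truth labels
#'
#' Decoy construction: each decoy sits inside the causal locus (except the
#' `off_locus` mode) and violates exactly one funnel stage — heterozygous
#' genotype, presence in a panel strain, absence from assembly B, position
#' outside the locus, or a LOW-impact consequence. Background variants are
#' placed outside the locus with mixed genotypes, impacts, panel sharing
#' and assembly presence. The causal variant passes every stage by
#' construction.
#'
#' @param spec A [variant_sim_spec()].
#' @return List with `case_a`, `case_b` (variant tables), `panel` (named
#'   list of per-strain variant tables), `truth` (`data.frame` of `chrom`,
#'   `pos` (assembly-A), `gene`, `class`) and `causal` (the planted causal
#'   record, assembly-A row).
#' @export
simulate_variant_callsets <- function(spec = variant_sim_spec()) {
  stopifnot(inherits(spec, "variant_sim_spec"))
  local_seed(spec$seed, {
    shift <- spec$assembly_shift
    if (is.null(shift)) {
      shift <- stats::setNames(
        sample(-50000:50000, length(spec$chrom_lengths), replace = TRUE),
        names(spec$chrom_lengths))
    }
    loc <- spec$causal_locus
    n_modes <- 5L
    n_total <- 1L + n_modes * spec$n_decoys_per_mode + spec$n_background

    in_locus_n <- 1L + 4L * spec$n_decoys_per_mode  # all but off_locus mode
    pos_in <- sample(seq(loc$start, loc$end), in_locus_n)
    # off-locus positions: anywhere outside the locus on any chromosome
    out_n <- spec$n_decoys_per_mode + spec$n_background
    out_chrom <- sample(names(spec$chrom_lengths), out_n, replace = TRUE)
    out_pos <- vapply(out_chrom, function(ch) {
      repeat {
        p <- sample.int(spec$chrom_lengths[[ch]], 1L)
        if (!(ch == loc$chrom && p >= loc$start && p <= loc$end)) return(p)
      }
    }, 0L)

    al <- random_alleles(n_total)
    gene <- sprintf("G%05d", seq_len(n_total))
    moderate_terms <- c("missense_variant", "conservative_inframe_insertion",
                        "disruptive_inframe_deletion")
    classes <- c("causal",
                 rep(c("decoy_het", "decoy_panel_shared",
                       "decoy_single_assembly_only", "decoy_low_impact"),
                     each = spec$n_decoys_per_mode),
                 rep("decoy_off_locus", spec$n_decoys_per_mode),
                 rep("background", spec$n_background))
    chrom <- c(rep(loc$chrom, in_locus_n), out_chrom)
    pos <- c(pos_in, out_pos)

    genotype <- rep("hom_alt", n_total)
    genotype[classes == "decoy_het"] <- "het"
    so <- sample(moderate_terms, n_total, replace = TRUE)
    so[classes == "decoy_low_impact"] <- "synonymous_variant"
    bg <- classes == "background"
    so[bg] <- sample(names(so_impact_table()), sum(bg), replace = TRUE)
    genotype[bg] <- sample(c("hom_alt", "het"), sum(bg), replace = TRUE)

    in_b <- rep(TRUE, n_total)
    in_b[classes == "decoy_single_assembly_only"] <- FALSE
    in_b[bg] <- stats::runif(sum(bg)) < 0.9
    in_panel <- rep(FALSE, n_total)
    in_panel[classes == "decoy_panel_shared"] <- TRUE
    in_panel[bg] <- stats::runif(sum(bg)) < 0.5

    case_a <- variant_records(chrom, pos, al$ref, al$alt,
                              genotype = genotype, gene = gene,
                              so_terms = so, assembly = spec$assembly_a)
    case_b <- variant_records(chrom[in_b],
                              pos[in_b] + shift[chrom[in_b]],
                              al$ref[in_b], al$alt[in_b],
                              genotype = genotype[in_b], gene = gene[in_b],
                              so_terms = so[in_b], assembly = spec$assembly_b)

    panel <- lapply(seq_len(spec$n_panel_strains), function(k) {
      priv_chrom <- sample(names(spec$chrom_lengths), spec$n_panel_private,
                           replace = TRUE)
      priv_pos <- vapply(priv_chrom, function(ch)
        sample.int(spec$chrom_lengths[[ch]], 1L), 0L)
      priv_al <- random_alleles(spec$n_panel_private)
      variant_records(priv_chrom, priv_pos, priv_al$ref, priv_al$alt,
                      genotype = sample(c("hom_alt", "het"),
                                        spec$n_panel_private, replace = TRUE),
                      gene = "", so_terms = "intergenic_variant",
                      assembly = spec$assembly_a)
    })
    names(panel) <- sprintf("PANEL%02d", seq_len(spec$n_panel_strains))
    # shared variants appear verbatim in at least one panel strain
    for (i in which(in_panel)) {
      k <- sample.int(spec$n_panel_strains, 1L)
      panel[[k]] <- rbind(panel[[k]],
                          variant_records(chrom[i], pos[i], al$ref[i], al$alt[i],
                                          genotype = sample(c("hom_alt", "het"), 1L),
                                          gene = gene[i], so_terms = so[i],
                                          assembly = spec$assembly_a))
    }

    truth <- data.frame(chrom = chrom, pos = pos, gene = gene,
                        class = classes, stringsAsFactors = FALSE)
    list(case_a = sort_variants(case_a), case_b = sort_variants(case_b),
         panel = lapply(panel, sort_variants),
         truth = truth,
         causal = case_a[case_a$gene == gene[classes == "causal"], ,
                         drop = FALSE],
         assembly_shift = shift)
  })
}

#' Simulate an RT-qPCR Ct table with planted group effects
#'
#' Ct values follow the delta-Ct model: the target cycle equals the
#' reference-gene cycle plus a gene-specific baseline offset minus
#' `log2(fold)` for the planted fold change of that (strain, timepoint)
#' group, plus Gaussian cycle noise.
#'
#' @param effects `data.frame` with columns `gene`, `strain`, `timepoint`,
#'   `fold`: the planted relative quantity of each group versus the
#'   reference timepoint (groups not listed have fold 1).
#' @param genes Genes to simulate; defaults to those in `effects`.
#' @param timepoints Sampling weeks. Default `c(4, 8, 10)`.
#' @param case_replicates,control_replicates Replicates per group (defaults
#'   4 and 3, the usual validation design).
#' @param reference_ct Reference-gene cycle. Default 20.
#' @param baseline_dct Baseline target-minus-reference cycles. Default 5.
#' @param noise_sd Gaussian noise on target cycles. Default 0.2.
#' @param seed Integer seed. Default 0.
#' @return A Ct table `data.frame` (see [read_ct_table()]).
#' @export
simulate_qpcr <- function(effects, genes = unique(effects$gene),
                          timepoints = c(4, 8, 10),
                          case_replicates = 4, control_replicates = 3,
                          reference_ct = 20, baseline_dct = 5,
                          noise_sd = 0.2, seed = 0L) {
  stopifnot(noise_sd >= 0, all(c("gene", "strain", "timepoint", "fold")
                               %in% names(effects)) || nrow(effects) == 0L)
  local_seed(seed, {
    rows <- list()
    for (g in genes) {
      for (st in c("case", "control")) {
        n_rep <- if (st == "case") case_replicates else control_replicates
        for (tp in timepoints) {
          hit <- effects[effects$gene == g & effects$strain == st &
                           effects$timepoint == tp, , drop = FALSE]
          fold <- if (nrow(hit) >= 1L) hit$fold[1L] else 1
          for (r in seq_len(n_rep)) {
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g,
              sample_id = sprintf("%s_%dwk_%d", st, tp, r),
              strain = st, timepoint = tp,
              ct_target = reference_ct + baseline_dct - log2(fold) +
                stats::rnorm(1L, 0, noise_sd),
              ct_reference = reference_ct,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
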