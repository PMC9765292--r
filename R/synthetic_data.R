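# Synthetic-data generator with planted ground truth.
#
# The generator emulates the screen's stated world: a circular annotated
# genome, a guide library, pooled-screen counts produced by ~12 generations
# of exponential growth under per-gene, condition-specific selection, and
# noisy luciferase growth curves with planted promoter-activity fold
# changes. Selection is parameterized per generation: a guide of gene g
# grows as 2^(G * (1 + s_g(condition) + eps)) so the expected guide log2
# fold change against mock is G * s_g. Guide-efficacy noise eps (sd
# sigma_guide) is drawn once per guide and applied in the dCas9-induced
# conditions (Ci, Ci+C) only — mock has no interference, and a guide's
# efficacy is a property of the guide, shared between induced conditions.

#' Simulation configuration
#'
#' Defaults restate the screen's conditions: a median of ~24 guides per
#' gene, ~12 generations of growth, 4 technical replicates and ~10 million
#' mapped reads per replicate (~40 million per pooled condition), mild
#' negative-binomial sequencing overdispersion, log-normal cloning
#' abundance spread, small guide-efficacy noise, and 5% luciferase
#' measurement noise.
#'
#' @param n_genes number of genes.
#' @param guides_per_gene mean guide count per gene (Poisson unless
#'   `fixed_guides = TRUE`).
#' @param fixed_guides if `TRUE`, every gene gets exactly `guides_per_gene`
#'   guides.
#' @param generations growth generations G (default 12).
#' @param reads_per_replicate sequencing depth per replicate (default 1e7).
#' @param replicates technical replicates per condition (default 4).
#' @param dispersion negative-binomial dispersion of sequencing noise
#'   (default 0.01; 0 degrades to multinomial sampling).
#' @param sigma_init log-normal sd of initial guide abundances (default 0.5).
#' @param sigma_guide sd of per-guide efficacy noise on the per-generation
#'   selection coefficient (default 0.02).
#' @param sigma_lux relative sd of luciferase noise (default 0.05).
#' @param seed RNG seed (mandatory for reproducible runs).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, guides_per_gene = 24, fixed_guides = FALSE,
                       generations = 12, reads_per_replicate = 1e7,
                       replicates = 4L, dispersion = 0.01, sigma_init = 0.5,
                       sigma_guide = 0.02, sigma_lux = 0.05, seed = 1L) {
  stopifnot(n_genes >= 0, guides_per_gene > 0, generations > 0,
            reads_per_replicate > 0, replicates >= 1L, dispersion >= 0,
            sigma_init > 0, sigma_guide >= 0, sigma_lux >= 0)
  structure(list(n_genes = as.integer(n_genes), guides_per_gene = guides_per_gene,
                 fixed_guides = isTRUE(fixed_guides),
                 generations = generations,
                 reads_per_replicate = reads_per_replicate,
                 replicates = as.integer(replicates), dispersion = dispersion,
                 sigma_init = sigma_init, sigma_guide = sigma_guide,
                 sigma_lux = sigma_lux, seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted per-gene ground truth
#'
#' Assigns class labels and per-generation selection coefficients:
#' `neutral` (all s = 0, reporter factor 1), `essential` (equal fitness cost
#' in both induced conditions), `competence_costly` (cost only when
#' competence is induced: s_ci ~ 0, s_cic = s_ci + s_delta < 0; these are
#' the screen's targets, with reporter factor > 1 because their inhibition
#' derepresses the comX promoter), and optionally `competence_required`
#' (activators carrying a fratricide-style penalty s_cic < 0 and reporter
#' factor < 1).
#'
#' @param genes character vector of gene identifiers.
#' @param n_costly number of competence-costly genes (default 50).
#' @param n_essential number of essential genes (default `round(0.15 *
#'   length(genes))`).
#' @param n_required number of competence-required genes (default 0).
#' @param s_delta competence-specific per-generation penalty of costly genes
#'   (default -0.25, an expected log2 fold-change shift of G * s_delta).
#' @param s_essential per-generation cost of essential genes in both induced
#'   conditions (default -0.3).
#' @param s_required fratricide penalty of competence-required genes under
#'   competence induction (default -0.2).
#' @param reporter_factor_costly promoter-activity factor of costly genes
#'   (default 2).
#' @param reporter_factor_required factor of required genes (default 0.5).
#' @param seed RNG seed for the class assignment.
#' @return data.frame `gene`, `class`, `s_mock`, `s_ci`, `s_cic`,
#'   `reporter_factor`.
#' @export
simulate_truth <- function(genes, n_costly = 50L,
                           n_essential = round(0.15 * length(genes)),
                           n_required = 0L, s_delta = -0.25,
                           s_essential = -0.3, s_required = -0.2,
                           reporter_factor_costly = 2,
                           reporter_factor_required = 0.5, seed = 1L) {
  n <- length(genes)
  stopifnot(n_costly + n_essential + n_required <= n)
  .with_seed(seed, {
    cls <- rep.int("neutral", n)
    pick <- sample.int(n, n_costly + n_essential + n_required)
    cls[pick[seq_len(n_costly)]] <- "competence_costly"
    if (n_essential) cls[pick[n_costly + seq_len(n_essential)]] <- "essential"
    if (n_required) cls[pick[n_costly + n_essential + seq_len(n_required)]] <- "competence_required"
  })
  s_ci <- ifelse(cls == "essential", s_essential, 0)
  s_cic <- s_ci + ifelse(cls == "competence_costly", s_delta,
                         ifelse(cls == "competence_required", s_required, 0))
  data.frame(gene = genes, class = cls,
             s_mock = 0, s_ci = s_ci, s_cic = s_cic,
             reporter_factor = ifelse(cls == "competence_costly",
                                      reporter_factor_costly,
                                      ifelse(cls == "competence_required",
                                             reporter_factor_required, 1)),
             stringsAsFactors = FALSE)
}

#' Simulate an annotated genome
#'
#' Random circular (or linear) sequence with non-overlapping CDSs on
#' alternating strands separated by intergenic gaps. The feature table is
#' the ground truth for design and I/O round trips.
#'
#' @param n_genes number of CDSs (0 gives an all-intergenic genome).
#' @param mean_cds_length mean CDS length in bp (default 900).
#' @param mean_intergenic mean intergenic gap in bp (default 120).
#' @param gc GC content of the random sequence (default 0.36, a typical
#'   streptococcal value).
#' @param circular logical (default `TRUE`).
#' @param seed RNG seed.
#' @param id replicon identifier.
#' @return an [annotated_genome()] whose features are the planted CDSs.
#' @export
simulate_genome <- function(n_genes = 100L, mean_cds_length = 900,
                            mean_intergenic = 120, gc = 0.36,
                            circular = TRUE, seed = 1L, id = "synthetic_chr") {
  stopifnot(n_genes >= 0, mean_cds_length >= 60, mean_intergenic >= 2, gc > 0, gc < 1)
  .with_seed(seed, {
    if (n_genes > 0L) {
      glen <- pmax(120L, 3L * round(stats::rlnorm(n_genes, log(mean_cds_length / 3), 0.3)))
      ig <- 2L + stats::rpois(n_genes, mean_intergenic - 2)
    } else {
      glen <- integer(0)
      ig <- max(23L, as.integer(mean_intergenic))
    }
    L <- as.integer(sum(glen) + sum(ig))
    if (n_genes > 0L && L < sum(glen)) stop("genes cannot fit requested length", call. = FALSE)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
                      collapse = "")
    features <- NULL
    if (n_genes > 0L) {
      # sequential layout: gap_i then gene_i
      pos <- 0L
      start <- integer(n_genes)
      for (i in seq_len(n_genes)) {
        pos <- pos + ig[i]
        start[i] <- pos
        pos <- pos + glen[i]
      }
      features <- data.frame(
        locus_tag = sprintf("SYN_%04d", seq_len(n_genes)),
        gene_name = NA_character_,
        kind = "CDS",
        strand = rep_len(c("+", "-"), n_genes),
        start = start, end = start + glen,
        stringsAsFactors = FALSE)
    }
    annotated_genome(id, sequence, circular, features)
  })
}

#' Fabricate a guide library directly from gene identifiers
#'
#' Bypasses genome design when only the counting/statistics layers are
#' exercised: random distinct spacers, each assigned to one gene with
#' `target_class = "cds_rule_pass"`.
#'
#' @param genes character vector of gene identifiers.
#' @param guides_per_gene mean (Poisson) or exact guide count per gene.
#' @param fixed_guides exact counts if `TRUE`.
#' @param seed RNG seed.
#' @return a `guide_library`.
#' @export
simulate_library <- function(genes, guides_per_gene = 24, fixed_guides = FALSE,
                             seed = 1L) {
  .with_seed(seed, {
    k <- if (fixed_guides) rep.int(as.integer(guides_per_gene), length(genes))
         else pmax(1L, stats::rpois(length(genes), guides_per_gene))
    n <- sum(k)
    repeat {
      spacers <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE), collapse = ""),
        character(1L))
      if (!anyDuplicated(spacers)) break
    }
    gene_of <- rep.int(genes, k)
    guides <- data.frame(spacer = spacers, pam = "AGG",
                         strand = rep_len(c("+", "-"), n),
                         start = seq_len(n) * 25L,
                         targets = paste0(gene_of, ":20"),
                         target_class = "cds_rule_pass",
                         multi_target = FALSE, copies = 1L,
                         stringsAsFactors = FALSE)
    structure(list(guides = guides, genome_id = "synthetic_direct",
                   genome_length = as.integer(n * 25L + 25L), circular = TRUE,
                   n_candidates = n, n_rejected = 0L, rna_rule = "cds"),
              class = "guide_library")
  })
}

#' Simulate pooled-screen counts under planted selection
#'
#' Guide i of gene g starts at a log-normal abundance `a_i` and grows to
#' `a_i * 2^(G * (1 + s_g(condition) + eps_i))`, with per-guide efficacy
#' noise `eps_i ~ N(0, sigma_guide)` applied in the induced conditions (Ci,
#' Ci+C). Reads per replicate are drawn negative-binomially (dispersion
#' `dispersion`) around the multinomial expectation at the configured
#' depth; dispersion 0 uses multinomial sampling. Guides without a gene
#' (intergenic) are neutral.
#'
#' @param lib a `guide_library`; every targeted gene must have a truth row.
#' @param truth data.frame from [simulate_truth()].
#' @param cfg a [sim_config()].
#' @param conditions condition labels simulated (default mock, Ci, CiC).
#' @return a `count_matrix` with `cfg$replicates` columns per condition; the
#'   truth table and expected log2 fold changes are attached as attributes
#'   `truth` and `expected_lfc`.
#' @export
simulate_screen_counts <- function(lib, truth, cfg,
                                   conditions = c("mock", "Ci", "CiC")) {
  stopifnot(inherits(lib, "guide_library"), inherits(cfg, "sim_config"))
  if (cfg$reads_per_replicate <= 0) stop("depth must be positive", call. = FALSE)
  idx <- library_gene_index(lib)
  first_gene <- idx$gene[match(unique(lib$guides$spacer), idx$spacer)]
  spacers <- unique(lib$guides$spacer)
  tg <- unique(idx$gene)
  missing_truth <- setdiff(tg, truth$gene)
  if (length(missing_truth)) {
    stop("truth table lacks genes: ",
         paste(utils::head(missing_truth, 5L), collapse = ", "), call. = FALSE)
  }
  m <- match(first_gene, truth$gene)
  s_of <- function(cond) {
    s <- switch(cond,
                mock = truth$s_mock[m], Ci = truth$s_ci[m], CiC = truth$s_cic[m],
                stop("unknown condition: ", cond, call. = FALSE))
    s[is.na(s)] <- 0  # intergenic / unassigned guides are neutral
    s
  }
  G <- cfg$generations
  n <- length(spacers)
  .with_seed(cfg$seed, {
    a <- stats::rlnorm(n, 0, cfg$sigma_init)
    eps <- stats::rnorm(n, 0, cfg$sigma_guide)
    counts <- NULL
    samples <- NULL
    expected_lfc <- list()
    for (cond in conditions) {
      induced <- cond != "mock"
      logw <- log2(a) + G * (1 + s_of(cond) + if (induced) eps else 0)
      p <- 2^(logw - max(logw))
      p <- p / sum(p)
      expected_lfc[[cond]] <- G * s_of(cond)
      for (r in seq_len(cfg$replicates)) {
        mu <- cfg$reads_per_replicate * p
        col <- if (cfg$dispersion > 0) {
          stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
        } else {
          as.integer(stats::rmultinom(1L, size = cfg$reads_per_replicate, prob = p))
        }
        counts <- cbind(counts, col)
        samples <- rbind(samples,
                         data.frame(sample = sprintf("%s_r%d", cond, r),
                                    condition = cond, replicate = as.character(r),
                                    stringsAsFactors = FALSE))
      }
    }
    rownames(counts) <- spacers
    colnames(counts) <- samples$sample
    storage.mode(counts) <- "integer"
    cm <- count_matrix(counts, samples)
    attr(cm, "truth") <- truth
    attr(cm, "expected_lfc") <- expected_lfc
    cm
  })
}

#' Write simulated amplicon FASTQ files for a count matrix
#'
#' Each count becomes one read `upstream + spacer + downstream`; the reads
#' of a sample are shuffled deterministically before writing.
#'
#' @param cm a `count_matrix`.
#' @param schema an [amplicon_schema()].
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the shuffling.
#' @return sample sheet data.frame (`sample`, `condition`, `replicate`,
#'   `fastq`) usable with [count_reads()].
#' @export
simulate_fastq <- function(cm, schema, dir, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), inherits(schema, "amplicon_schema"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spacers <- rownames(cm$counts)
  .with_seed(seed, {
    paths <- vapply(seq_len(ncol(cm$counts)), function(j) {
      cnt <- cm$counts[, j]
      reads <- rep.int(paste0(schema$upstream, spacers, schema$downstream), cnt)
      reads <- sample(reads)
      fp <- file.path(dir, paste0(cm$samples$sample[j], ".fastq"))
      ss <- Biostrings::DNAStringSet(reads)
      names(ss) <- sprintf("read_%07d", seq_along(reads))
      Biostrings::writeXStringSet(
        ss, fp, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
      fp
    }, character(1L))
  })
  cbind(cm$samples, fastq = paths, stringsAsFactors = FALSE)
}

#' Simulate reporter clones and luciferase time series
#'
#' OD600 follows a logistic curve from 0.05 to `od_max`; RLU is
#' `base_activity * reporter_factor * od * (1 + eta)` with relative noise
#' `eta ~ N(0, sigma_lux)`, sampled every `interval_min` minutes over
#' `duration_min`. A no-gRNA reference clone (factor 1) is appended when
#' absent.
#'
#' @param clones data.frame `clone_id`, `spacer`, `reporter_factor`.
#' @param cfg a [sim_config()] (`sigma_lux`, `seed`).
#' @param duration_min assay duration in minutes (default 480 = 8 h).
#' @param interval_min sampling interval (default 10 min).
#' @param od0,od_max,doubling_min growth-curve parameters (defaults 0.05,
#'   1.0, 45 min).
#' @param base_activity RLU per OD unit of the reference promoter state
#'   (default 1000).
#' @return list with `clones` (sheet incl. the reference) and `timeseries`
#'   (long data.frame `clone_id`, `t`, `od600`, `rlu`).
#' @export
simulate_reporter <- function(clones, cfg, duration_min = 480, interval_min = 10,
                              od0 = 0.05, od_max = 1.0, doubling_min = 45,
                              base_activity = 1000) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("clone_id", "spacer", "reporter_factor") %in% names(clones)))
  if (!"reference" %in% clones$clone_id) {
    clones <- rbind(clones,
                    data.frame(clone_id = "reference", spacer = NA_character_,
                               reporter_factor = 1, stringsAsFactors = FALSE))
  }
  t <- seq(0, duration_min, by = interval_min)
  r <- log(2) / doubling_min
  od <- od_max * od0 / (od0 + (od_max - od0) * exp(-r * t))
  .with_seed(cfg$seed, {
    ts <- do.call(rbind, lapply(seq_len(nrow(clones)), function(i) {
      eta <- stats::rnorm(length(t), 0, cfg$sigma_lux)
      data.frame(clone_id = clones$clone_id[i], t = t, od600 = od,
                 rlu = base_activity * clones$reporter_factor[i] * od * (1 + eta),
                 stringsAsFactors = FALSE)
    }))
    list(clones = clones, timeseries = ts)
  })
}

#' Simulate a COG assignment table for a gene set
#'
#' Categories are drawn from a rough bacterial genome composition; a small
#' fraction of genes is left unassigned (absent from the table).
#'
#' @param genes character vector of gene identifiers.
#' @param unassigned_frac fraction of genes with no COG assignment
#'   (default 0.08).
#' @param seed RNG seed.
#' @return a `cog_table`.
#' @export
simulate_cog_table <- function(genes, unassigned_frac = 0.08, seed = 1L) {
  cats <- c(J = 0.08, K = 0.07, L = 0.05, D = 0.02, V = 0.02, T = 0.04,
            M = 0.05, N = 0.01, U = 0.02, O = 0.04, C = 0.05, G = 0.09,
            E = 0.10, F = 0.04, H = 0.05, I = 0.03, P = 0.06, Q = 0.01,
            R = 0.10, S = 0.07)
  .with_seed(seed, {
    keep <- stats::runif(length(genes)) > unassigned_frac
    assigned <- genes[keep]
    category <- sample(names(cats), length(assigned), replace = TRUE,
                       prob = cats / sum(cats))
    cog_table(data.frame(gene = assigned, category = category,
                         stringsAsFactors = FALSE))
  })
}
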