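#' Configure the synthetic community generator
#'
#' Describes a factorial soil-survey design (habitats x treatments x
#' replicate blocks) and the statistical structure to plant in the generated
#' OTU counts: correlated OTU blocks tied to one habitat, multiplicative
#' treatment effects on chosen OTUs, and signed OTU-gene links. Counts are
#' produced by a log-normal latent-abundance model closed compositionally by
#' multinomial sampling at each sample's library size.
#'
#' Within a planted block, pairwise correlation of log-abundances across the
#' tagged habitat's samples is induced by a shared Gaussian factor: each
#' member's per-sample log noise in that habitat is
#' `member_sd * (sqrt(rho) * f + sqrt(1 - rho) * eps)` with `f` shared across
#' members and `eps` idiosyncratic, giving latent pairwise correlation `rho`
#' at total log variance `member_sd^2` (the mapping to the correlation of observed
#' relative abundances is approximate: sampling noise and the untagged
#' habitat's samples dilute it, the shared habitat preference strengthens
#' it). Members are additionally `habitat_fold` times more abundant in the
#' tagged habitat (their planted habitat preference), and their baseline
#' log-abundance is pinned at `member_base_log` (default 0, the median of
#' the baseline distribution) so that block recovery tests the method
#' rather than the baseline-abundance lottery, while the block stays a
#' modest share of the community (a dominant block would correlate all
#' bystanders through compositional closure). A block may name
#' one `hub` member whose factor loading is multiplied by `hub_boost`
#' (capped so the loading stays below 1) and whose baseline log-abundance is
#' raised by `hub_base_add` — hub taxa are abundant, well-connected members,
#' and the higher depth coverage reduces sampling attenuation of their
#' associations, making the hub's edges the strongest in the block.
#'
#' @param n_otus Number of OTUs.
#' @param treatments,habitats,n_replicates The factorial design; defaults are
#'   4 nitrogen treatments (none, mineral-N, manure, both) x 2 soil habitats
#'   x 4 replicate blocks = 32 samples.
#' @param depth_range Length-2 integer vector: uniform range of library sizes.
#' @param base_log_mean,base_log_sd Mean/sd of each OTU's baseline natural-log
#'   abundance (drawn once per OTU).
#' @param noise_sd Optional log-normal overdispersion: sd of per-sample
#'   log-abundance noise added to every OTU. Default 0, i.e. off — the only
#'   sample-to-sample variation outside planted structure is the multinomial
#'   closure itself, so count-based tests are exactly calibrated under the
#'   null. Block members always carry their own within-habitat noise (see
#'   `member_sd` below).
#' @param blocks List of planted blocks, each
#'   `list(habitat =, members =, rho =, hub = NULL, hub_boost = 1.1,
#'   habitat_fold = 4, member_base_log = 0, member_sd = 0.7,
#'   hub_base_add = 1)`; `members` are
#'   OTU ids (`"OTU_7"`) or indices, `rho` in (0, 1]; `member_sd` is the
#'   members' within-tagged-habitat log-noise sd that the shared factor
#'   decomposes; set `member_base_log = NULL` to keep the randomly drawn
#'   baselines.
#' @param treatment_effects List of `list(otu =, treatment =, fold_change =)`
#'   with `fold_change > 0`, applied multiplicatively to the latent abundance
#'   in samples of that treatment.
#' @param gene_links List of `list(gene =, otu =, sign = c(-1, 1), rho =)`
#'   consumed by [generate_gene_abundances()].
#' @param seed Integer seed; the same config and seed reproduce the data
#'   exactly.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_otus = 300,
                         treatments = c("0", "N", "M", "NM"),
                         habitats = c("rhizosphere", "bulk"),
                         n_replicates = 4,
                         depth_range = c(5000, 20000),
                         base_log_mean = 0, base_log_sd = 1.5,
                         noise_sd = 0,
                         blocks = list(),
                         treatment_effects = list(),
                         gene_links = list(),
                         seed = 1) {
  if (n_otus < 1) abort("`n_otus` must be positive.")
  if (length(treatments) < 1 || length(habitats) < 1 || n_replicates < 1) {
    abort("Empty design: need >= 1 treatment, habitat and replicate.")
  }
  if (length(depth_range) != 2 || depth_range[1] < 1 ||
      depth_range[2] < depth_range[1]) {
    abort("`depth_range` must be c(min, max) with 1 <= min <= max.")
  }
  ids <- paste0("OTU_", seq_len(n_otus))
  norm_members <- function(m) {
    if (is.numeric(m)) m <- ids[m]
    if (any(!m %in% ids)) abort("Block member outside 1..n_otus.")
    m
  }
  seen <- character(0)
  blocks <- lapply(blocks, function(b) {
    b$members <- norm_members(b$members)
    if (length(b$members) > n_otus) abort("Block larger than n_otus.")
    if (any(b$members %in% seen)) abort("Planted blocks must be disjoint.")
    seen <<- c(seen, b$members)
    if (is.null(b$rho) || b$rho <= 0 || b$rho > 1) abort("Block rho must be in (0, 1].")
    if (!b$habitat %in% habitats) abort("Block habitat not in design.")
    if (!is.null(b$hub)) {
      if (is.numeric(b$hub)) b$hub <- ids[b$hub]
      if (!b$hub %in% b$members) abort("Block hub must be a member.")
    }
    b$hub_boost <- b$hub_boost %||% 1.1
    b$habitat_fold <- b$habitat_fold %||% 4
    if (b$habitat_fold <= 0) abort("habitat_fold must be > 0.")
    if (!("member_base_log" %in% names(b))) b$member_base_log <- 0
    b$member_sd <- b$member_sd %||% 0.7
    b$hub_base_add <- b$hub_base_add %||% 1
    b
  })
  treatment_effects <- lapply(treatment_effects, function(e) {
    if (is.numeric(e$otu)) e$otu <- ids[e$otu]
    if (!e$otu %in% ids) abort("Treatment-effect OTU outside table.")
    if (!e$treatment %in% treatments) abort("Unknown treatment in effect.")
    if (is.null(e$fold_change) || e$fold_change <= 0) {
      abort("fold_change must be > 0.")
    }
    e
  })
  gene_links <- lapply(gene_links, function(l) {
    if (is.numeric(l$otu)) l$otu <- ids[l$otu]
    if (!l$sign %in% c(-1, 1)) abort("Gene-link sign must be -1 or +1.")
    if (is.null(l$rho) || l$rho <= 0 || l$rho > 1) abort("Gene-link rho must be in (0, 1].")
    l
  })
  structure(list(n_otus = n_otus, otu_ids = ids, treatments = treatments,
                 habitats = habitats, n_replicates = n_replicates,
                 depth_range = depth_range, base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd, noise_sd = noise_sd,
                 blocks = blocks, treatment_effects = treatment_effects,
                 gene_links = gene_links, seed = seed),
            class = "synth_config")
}

synth_design <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_replicates),
                   treatment = config$treatments,
                   habitat = config$habitats,
                   stringsAsFactors = FALSE)
  tibble(sample_id = paste(g$habitat, g$treatment, g$replicate, sep = "_"),
         habitat = g$habitat, treatment = g$treatment,
         block = paste0("B", g$replicate))
}

synth_taxonomy <- function(n) {
  phyla <- c("Acidobacteria", "Proteobacteria", "Actinobacteria",
             "Verrucomicrobia", "Gemmatimonadetes", "Latescibacteria",
             "Bacteroidetes", "Chloroflexi", "Planctomycetes", "Nitrospirae")
  ph <- sample(phyla, n, replace = TRUE)
  paste0("Bacteria;", ph, ";class_", sample(40, n, TRUE),
         ";order_", sample(120, n, TRUE), ";family_", sample(250, n, TRUE))
}

#' Generate a synthetic OTU table with planted structure
#'
#' Draws per-OTU baseline log-abundances, adds the planted block factors (on
#' the tagged habitat's samples), applies treatment fold-changes, adds
#' per-sample noise, converts to per-sample composition and draws multinomial
#' counts at a library size uniform in `depth_range`. Column sums equal the
#' drawn library sizes exactly.
#'
#' @param config A [synth_config()].
#' @return A list with `table` (an [otu_table()] with taxonomy and metadata)
#'   and `truth` (a `synth_truth` record of what was planted: block
#'   memberships, differentially abundant OTUs per treatment and gene links).
#' @export
generate_otu_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_otus
  md <- synth_design(config)
  s <- nrow(md)
  # baseline drawn first so configs differing only in planted effects share it
  base <- rnorm(n, config$base_log_mean, config$base_log_sd)
  taxonomy <- synth_taxonomy(n)
  depths <- sample(seq(config$depth_range[1], config$depth_range[2]), s,
                   replace = TRUE)
  block_f <- lapply(config$blocks, function(b) rnorm(s))
  eps <- matrix(rnorm(n * s), n, s)  # standard-normal idiosyncratic noise
  noise <- config$noise_sd * eps
  loglam <- matrix(base, n, s)
  for (bi in seq_along(config$blocks)) {
    b <- config$blocks[[bi]]
    f <- block_f[[bi]]
    in_hab <- md$habitat == b$habitat
    for (m in b$members) {
      i <- match(m, config$otu_ids)
      if (!is.null(b$member_base_log)) loglam[i, ] <- b$member_base_log
      lam <- sqrt(b$rho)
      if (!is.null(b$hub) && m == b$hub) {
        lam <- min(lam * b$hub_boost, 0.995)
        loglam[i, ] <- loglam[i, ] + b$hub_base_add
      }
      # shared-factor decomposition at total log variance member_sd^2
      noise[i, in_hab] <- b$member_sd *
        (lam * f[in_hab] + sqrt(1 - lam^2) * eps[i, in_hab])
      loglam[i, in_hab] <- loglam[i, in_hab] + log(b$habitat_fold)
    }
  }
  for (e in config$treatment_effects) {
    i <- match(e$otu, config$otu_ids)
    j <- md$treatment == e$treatment
    loglam[i, j] <- loglam[i, j] + log(e$fold_change)
  }
  loglam <- loglam + noise
  counts <- matrix(0, n, s, dimnames = list(config$otu_ids, md$sample_id))
  for (j in seq_len(s)) {
    w <- exp(loglam[, j] - max(loglam[, j]))
    counts[, j] <- rmultinom(1, depths[j], w / sum(w))
  }
  truth <- structure(list(
    blocks = lapply(config$blocks, function(b)
      b[c("habitat", "members", "rho", "hub")]),
    diff_otus = if (length(config$treatment_effects) > 0) {
      tibble(otu_id = vapply(config$treatment_effects, `[[`, "", "otu"),
             treatment = vapply(config$treatment_effects, `[[`, "", "treatment"),
             fold_change = vapply(config$treatment_effects, `[[`, 1, "fold_change"))
    } else tibble(otu_id = character(), treatment = character(),
                  fold_change = numeric()),
    gene_links = if (length(config$gene_links) > 0) {
      tibble(gene = vapply(config$gene_links, `[[`, "", "gene"),
             otu_id = vapply(config$gene_links, `[[`, "", "otu"),
             sign = vapply(config$gene_links, `[[`, 1, "sign"),
             rho = vapply(config$gene_links, `[[`, 1, "rho"))
    } else tibble(gene = character(), otu_id = character(),
                  sign = numeric(), rho = numeric())),
    class = "synth_truth")
  list(table = otu_table(counts, taxonomy = taxonomy, metadata = md),
       truth = truth)
}

#' Generate synthetic qPCR gene abundances
#'
#' For each nitrogen-cycle marker gene, builds a per-sample positive value as
#' a monotone (log-linear) function of the linked OTUs' relative abundances,
#' with the planted sign and a Gaussian noise component sized so the latent
#' correlation with a single linked OTU is approximately the planted `rho`;
#' unlinked genes are independent log-normal noise. Values are expressed as
#' percent of 16S rRNA gene copies.
#'
#' @param config A [synth_config()] (its `gene_links` are used).
#' @param table The [otu_table()] produced from `config`.
#' @param genes Character vector of gene names to emit.
#' @param habitat Habitat to restrict samples to (qPCR is typically run on
#'   bulk soil only); `NULL` keeps all samples.
#' @return A tibble (`sample_id` + one column per gene) with attribute
#'   `unit = "percent_16S"`.
#' @export
generate_gene_abundances <- function(
    config, table,
    genes = c("amoA_bacterial", "amoA_archaeal", "nirK", "nirS",
              "nosZ_I", "nosZ_II"),
    habitat = "bulk") {
  stopifnot(inherits(config, "synth_config"), inherits(table, "otu_table"))
  link_otus <- vapply(config$gene_links, `[[`, "", "otu")
  if (any(!link_otus %in% otu_ids(table))) {
    abort("Gene link references an OTU absent from the table.")
  }
  set.seed(config$seed + 1L)
  keep <- rep(TRUE, ncol(table$counts))
  if (!is.null(habitat)) {
    if (is.null(table$metadata)) abort("Habitat filter needs sample metadata.")
    keep <- table$metadata$habitat == habitat
    if (!any(keep)) abort(paste0("No samples in habitat '", habitat, "'."))
  }
  sub <- subset_samples_tab(table, keep)
  props <- to_relative(sub)$proportions
  floor_p <- min(props[props > 0]) / 2
  base_level <- c(amoA_bacterial = 0.05, amoA_archaeal = 1, nirK = 0.5,
                  nirS = 0.3, nosZ_I = 0.2, nosZ_II = 0.8)
  s <- ncol(props)
  out <- tibble(sample_id = colnames(props))
  for (g in genes) {
    links <- Filter(function(l) l$gene == g, config$gene_links)
    z <- rnorm(s)
    if (length(links) == 0) {
      latent <- z
    } else {
      sig <- 0
      rho2 <- 0
      for (l in links) {
        x <- log(props[l$otu, ] + floor_p)
        x <- (x - mean(x)) / max(sd(x), 1e-12)
        sig <- sig + l$sign * l$rho * x
        rho2 <- rho2 + l$rho^2
      }
      latent <- sig + sqrt(max(1 - rho2, 0.02)) * z
    }
    lvl <- if (g %in% names(base_level)) base_level[[g]] else 0.2
    out[[g]] <- unname(lvl * exp(0.6 * latent))
  }
  attr(out, "unit") <- "percent_16S"
  out
}

#' Write a synthetic dataset to a directory
#'
#' Emits the OTU table as QIIME-classic TSV and (when biomformat is
#' available) BIOM-JSON, the metadata as a mapping TSV, the gene table as
#' TSV, and the ground truth as JSON.
#'
#' @param sim Result of [generate_otu_table()].
#' @param dir Output directory (created if needed).
#' @param genes Optional gene tibble from [generate_gene_abundances()].
#' @return Invisibly, the directory.
#' @export
write_synthetic_dataset <- function(sim, dir, genes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table, file.path(dir, "otu_table.tsv"), "classic_tsv")
  if (requireNamespace("biomformat", quietly = TRUE)) {
    write_otu_table(sim$table, file.path(dir, "otu_table.biom"), "biom_json")
  }
  write_mapping_file(sim$table$metadata, file.path(dir, "mapping.tsv"))
  if (!is.null(genes)) write_gene_table(genes, file.path(dir, "genes.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(blocks = truth$blocks, diff_otus = truth$diff_otus,
         gene_links = truth$gene_links),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
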