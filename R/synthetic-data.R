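# Synthetic cohort generator: genome, annotation, Alu-like repeat track,
# circRNA truth set, cohort count matrices, and pre-aligned junction reads.
# Every downstream stage of the pipeline is testable against these outputs
# with no external download.

#' Simulation specification
#'
#' Bundles every parameter of the synthetic cohort. The seed fully determines
#' all generated output (genome bytes included).
#'
#' @param n_genes number of genes to generate.
#' @param exons_per_gene_range integer pair, inclusive range of exon counts.
#' @param exon_len_range integer pair, exon length range (nt).
#' @param intron_len_range integer pair, intron length range (nt). Must allow
#'   room for the 300-nt Alu-like insert when `alu_seed_fraction > 0`.
#' @param alu_seed_fraction fraction of introns receiving an Alu-like insert;
#'   introns flanking truth circRNA exons are seeded preferentially
#'   (probability `min(1, 3 * alu_seed_fraction)`).
#' @param n_samples_per_group named integer vector: samples per group label.
#' @param circ_fraction fraction of genes producing a truth circRNA.
#' @param suppressed_group group label whose circRNA counts are multiplied by
#'   `suppression_factor` (must name exactly one group).
#' @param suppression_factor multiplier (> 0) on circRNA count means in the
#'   suppressed group; 1 plants no effect.
#' @param nb_dispersion negative-binomial dispersion of all counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param mean_gene_count mean linear junction count per gene at library
#'   factor 1.
#' @param n_specific number of truth circRNAs elevated in the focal cohort
#'   relative to control cohorts.
#' @param specific_fold fold elevation (> 1) of the specific circRNAs in the
#'   focal cohort.
#' @param flank_len_factor multiplier on the length draw of introns flanking
#'   truth circRNA exons (circRNA-flanking introns are longer than average).
#' @param seed integer seed; determines every output byte.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 200L,
                     exons_per_gene_range = c(4L, 9L),
                     exon_len_range = c(100L, 300L),
                     intron_len_range = c(400L, 3000L),
                     alu_seed_fraction = 0.3,
                     n_samples_per_group = c(MNA = 20L, HR_nMNA = 20L),
                     circ_fraction = 0.3,
                     suppressed_group = "MNA",
                     suppression_factor = 0.5,
                     nb_dispersion = 0.2,
                     mean_gene_count = 200,
                     n_specific = 10L,
                     specific_fold = 8,
                     flank_len_factor = 2,
                     seed = 1L) {
  spec <- list(
    n_genes = as.integer(n_genes),
    exons_per_gene_range = as.integer(exons_per_gene_range),
    exon_len_range = as.integer(exon_len_range),
    intron_len_range = as.integer(intron_len_range),
    alu_seed_fraction = alu_seed_fraction,
    n_samples_per_group = n_samples_per_group,
    circ_fraction = circ_fraction,
    suppressed_group = suppressed_group,
    suppression_factor = suppression_factor,
    nb_dispersion = nb_dispersion,
    mean_gene_count = mean_gene_count,
    n_specific = as.integer(n_specific),
    specific_fold = specific_fold,
    flank_len_factor = flank_len_factor,
    seed = as.integer(seed))
  class(spec) <- "sim_spec"
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_genes < 1L) stop("sim_spec: n_genes must be >= 1")
  for (f in c("exons_per_gene_range", "exon_len_range", "intron_len_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2])
      stop("sim_spec: ", f, " must be an increasing positive pair")
  }
  if (spec$exons_per_gene_range[1] < 4L)
    stop("sim_spec: genes need >= 4 exons so circRNAs have flanking introns ",
         "and external linear junctions")
  if (spec$alu_seed_fraction < 0 || spec$alu_seed_fraction > 1)
    stop("sim_spec: alu_seed_fraction must lie in [0, 1]")
  if (spec$alu_seed_fraction > 0 && spec$intron_len_range[1] < 320L)
    stop("sim_spec: introns must be >= 320 nt to host the 300-nt Alu insert")
  if (is.null(names(spec$n_samples_per_group)) ||
      any(!nzchar(names(spec$n_samples_per_group))) ||
      any(spec$n_samples_per_group < 1L))
    stop("sim_spec: n_samples_per_group must be a named positive vector")
  if (!spec$suppressed_group %in% names(spec$n_samples_per_group))
    stop("sim_spec: suppressed_group '", spec$suppressed_group,
         "' is not a group label")
  if (spec$circ_fraction < 0 || spec$circ_fraction > 1)
    stop("sim_spec: circ_fraction must lie in [0, 1]")
  if (spec$suppression_factor <= 0)
    stop("sim_spec: suppression_factor must be > 0")
  if (spec$nb_dispersion < 0)
    stop("sim_spec: nb_dispersion must be >= 0")
  if (spec$mean_gene_count <= 0)
    stop("sim_spec: mean_gene_count must be > 0")
  if (spec$specific_fold <= 1)
    stop("sim_spec: specific_fold must be > 1")
  invisible(spec)
}

# run expr with a private RNG stream, restoring the caller's RNG state
with_rng <- function(seed, expr) {
  genv <- globalenv()
  has_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

# fixed 300-nt Alu-like sequence (single synthetic subfamily; only interval
# overlap matters downstream)
alu_like_sequence <- function() {
  with_rng(300L, paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                              prob = c(0.3, 0.25, 0.25, 0.2)), collapse = ""))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integers on [a, b] (safe when a == b, unlike sample())
rint <- function(a, b, n = 1L) {
  a + sample.int(b - a + 1L, n, replace = TRUE) - 1L
}

#' Generate the synthetic genome, annotation, repeat track, and truth set
#'
#' Lays out `n_genes` non-overlapping genes (one chromosome per ~50 genes),
#' each with exons and introns drawn from the spec ranges and a random strand.
#' A `circ_fraction` of genes carry one truth circRNA spanning an internal
#' exon block (so flanking introns and external linear junctions always
#' exist). Introns flanking truth circRNA exons are drawn
#' `flank_len_factor`-fold longer and are preferentially seeded with a fixed
#' 300-nt Alu-like insert; other introns are seeded at `alu_seed_fraction`.
#'
#' @param spec a [sim_spec()].
#' @return object of class `circ_sim` with elements `genome`
#'   (`Biostrings::DNAStringSet`), `annotation` (exon table: gene_id,
#'   transcript_id, exon_number, chrom, start, end, strand; 1-based
#'   inclusive), `genes`, `repeats` (`GenomicRanges::GRanges`), and `truth`
#'   (circ_records data.frame, specific_ids, suppressed_group).
#' @export
generate_annotation <- function(spec) {
  validate_sim_spec(spec)
  with_rng(derive_seed(spec$seed, 1L), {
    nuc <- c("A", "C", "G", "T")
    alu <- alu_like_sequence()
    genes_per_chrom <- 50L
    n_chrom <- ceiling(spec$n_genes / genes_per_chrom)
    chrom_of <- rep(sprintf("chrS%d", seq_len(n_chrom)),
                    each = genes_per_chrom)[seq_len(spec$n_genes)]
    gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))

    # choose circ-producing genes and their exon spans up front so intron
    # drawing can favor the flanks
    n_circ <- min(spec$n_genes, ceiling(spec$circ_fraction * spec$n_genes))
    circ_gene_idx <- if (n_circ > 0) sort(sample.int(spec$n_genes, n_circ))
                     else integer(0)

    exon_rows <- vector("list", spec$n_genes)
    gene_rows <- vector("list", spec$n_genes)
    truth_rows <- list()
    repeat_rows <- list()
    chrom_seq <- stats::setNames(vector("list", n_chrom),
                                 sprintf("chrS%d", seq_len(n_chrom)))
    for (nm in names(chrom_seq)) chrom_seq[[nm]] <- character(0)
    cursor <- stats::setNames(rep(1000L, n_chrom), names(chrom_seq))
    for (nm in names(chrom_seq)) chrom_seq[[nm]] <- list(rand_dna(999L))

    p_flank_alu <- min(1, 3 * spec$alu_seed_fraction)

    for (g in seq_len(spec$n_genes)) {
      chrom <- chrom_of[g]
      k <- rint(spec$exons_per_gene_range[1], spec$exons_per_gene_range[2])
      strand <- sample(c("+", "-"), 1L)
      is_circ_gene <- g %in% circ_gene_idx
      # acceptor/donor exon numbers in transcript order; circ genes carry at
      # least six exons so flanking introns, external linear junctions, and
      # non-flanking control-intron material all exist
      acc <- don <- NA_integer_
      if (is_circ_gene) {
        k <- max(k, 7L)
        acc <- rint(4L, k - 3L)
        don <- rint(acc, k - 3L)
      }
      exon_len <- rint(spec$exon_len_range[1], spec$exon_len_range[2], k)
      intron_len <- rint(spec$intron_len_range[1], spec$intron_len_range[2],
                         k - 1L)
      # transcript-order intron j sits between exon_number j and j+1
      flank_introns_tx <- if (is_circ_gene) c(acc - 1L, don) else integer(0)
      intron_len[flank_introns_tx] <-
        as.integer(round(intron_len[flank_introns_tx] *
                         spec$flank_len_factor))
      if (is_circ_gene) {
        # make each adjacent flank strictly the longest intron on its side
        # (so it is the one selected as the flank), and raise the side's
        # remaining introns - each staying below the flank - until they
        # cumulate past it, guaranteeing length-matched control material
        for (side in list(c(acc - 1L, seq_len(acc - 2L)),
                          c(don, don + seq_len(k - 1L - don)))) {
          fi <- side[1]; rest <- side[-1]
          f <- max(intron_len[fi], max(intron_len[rest]) + 1L)
          intron_len[fi] <- f
          n_rest <- length(rest)
          if (sum(intron_len[rest]) < f)
            intron_len[rest] <- pmax(intron_len[rest],
                                     as.integer(ceiling((f + n_rest) /
                                                          n_rest)))
        }
      }

      # genomic order: exon_number runs left->right on '+', right->left on '-'
      exon_num_genomic <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      exon_len_genomic <- exon_len[exon_num_genomic]
      intron_num_tx_genomic <- if (strand == "+") seq_len(k - 1L)
                               else rev(seq_len(k - 1L))
      intron_len_genomic <- intron_len[intron_num_tx_genomic]

      gstart <- cursor[chrom]
      starts <- integer(k); ends <- integer(k)
      pos <- gstart
      pieces <- character(2L * k - 1L)
      intron_coords <- matrix(0L, nrow = k - 1L, ncol = 2L)
      for (i in seq_len(k)) {
        starts[i] <- pos
        ends[i] <- pos + exon_len_genomic[i] - 1L
        pieces[2L * i - 1L] <- rand_dna(exon_len_genomic[i])
        pos <- ends[i] + 1L
        if (i < k) {
          il <- intron_len_genomic[i]
          intron_coords[i, ] <- c(pos, pos + il - 1L)
          seq_i <- rand_dna(il)
          # Alu seeding: flanks of circ exons preferred
          is_flank <- intron_num_tx_genomic[i] %in% flank_introns_tx
          p_alu <- if (is_flank) p_flank_alu else spec$alu_seed_fraction
          if (stats::runif(1) < p_alu && il >= 300L) {
            off <- as.integer(floor((il - 300L) / 2))
            substr(seq_i, off + 1L, off + 300L) <- alu
            repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
              chrom = chrom, start = pos + off, end = pos + off + 299L,
              name = "AluSyn", strand = sample(c("+", "-"), 1L),
              stringsAsFactors = FALSE)
          }
          pieces[2L * i] <- seq_i
          pos <- pos + il
        }
      }
      gend <- pos - 1L
      chrom_seq[[chrom]][[length(chrom_seq[[chrom]]) + 1L]] <-
        paste(pieces, collapse = "")
      gap <- sample(500:2000, 1L)
      chrom_seq[[chrom]][[length(chrom_seq[[chrom]]) + 1L]] <- rand_dna(gap)
      cursor[chrom] <- gend + gap + 1L

      exon_rows[[g]] <- data.frame(
        gene_id = gene_ids[g],
        transcript_id = paste0(gene_ids[g], ".t1"),
        exon_number = exon_num_genomic,
        chrom = chrom, start = starts, end = ends, strand = strand,
        stringsAsFactors = FALSE)
      gene_rows[[g]] <- data.frame(
        gene_id = gene_ids[g], chrom = chrom, start = gstart, end = gend,
        strand = strand, n_exons = k, stringsAsFactors = FALSE)

      if (is_circ_gene) {
        span_ex <- exon_rows[[g]][exon_rows[[g]]$exon_number %in% acc:don, ]
        cstart <- min(span_ex$start); cend <- max(span_ex$end)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          circ_id = sprintf("%s:%d-%d:%s", chrom, cstart, cend, strand),
          gene_id = gene_ids[g], acceptor_exon = acc, donor_exon = don,
          chrom = chrom, start = cstart, end = cend, strand = strand,
          stringsAsFactors = FALSE)
      }
    }

    genome <- Biostrings::DNAStringSet(vapply(
      chrom_seq, function(p) paste(unlist(p), collapse = ""), character(1)))
    annotation <- do.call(rbind, exon_rows)
    genes <- do.call(rbind, gene_rows)
    # expression means shared by every simulated cohort
    genes$base_mean <- spec$mean_gene_count *
      stats::rlnorm(nrow(genes), meanlog = -0.125, sdlog = 0.5)
    truth <- do.call(rbind, truth_rows)
    if (is.null(truth)) truth <- data.frame()
    if (nrow(truth) > 0) {
      truth$base_mean <- genes$base_mean[match(truth$gene_id, genes$gene_id)] *
        stats::runif(nrow(truth), 0.05, 0.3)
      n_spec <- min(spec$n_specific, nrow(truth))
      specific_ids <- if (n_spec > 0)
        sort(sample(truth$circ_id, n_spec)) else character(0)
      truth$specific <- truth$circ_id %in% specific_ids
    } else specific_ids <- character(0)

    repeats <- if (length(repeat_rows) > 0) {
      rr <- do.call(rbind, repeat_rows)
      GenomicRanges::GRanges(rr$chrom,
                             IRanges::IRanges(rr$start, rr$end),
                             strand = rr$strand, name = rr$name)
    } else GenomicRanges::GRanges()

    structure(list(
      genome = genome, annotation = annotation, genes = genes,
      repeats = repeats,
      truth = list(circ_records = truth, specific_ids = specific_ids,
                   suppressed_group = spec$suppressed_group),
      spec = spec), class = "circ_sim")
  })
}

#' @export
print.circ_sim <- function(x, ...) {
  cat("circ_sim:", length(x$genome), "chromosomes,",
      nrow(x$genes), "genes,",
      nrow(x$truth$circ_records), "truth circRNAs (",
      length(x$truth$specific_ids), "cohort-specific ),",
      length(x$repeats), "Alu-like repeats\n")
  invisible(x)
}

#' Derive the intron intervals of the annotation
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated by exact coordinates within a gene.
#'
#' @param annotation exon table as in [generate_annotation()].
#' @return data.frame: gene_id, chrom, start, end, strand, length, and
#'   `tx_intron` (transcript-order intron index of the first transcript
#'   carrying it).
#' @export
annotation_introns <- function(annotation) {
  pieces <- lapply(split(annotation, annotation$transcript_id), function(tx) {
    tx <- tx[order(tx$exon_number), ]
    if (nrow(tx) < 2L) return(NULL)
    gs <- if (tx$strand[1] == "+") tx$end[-nrow(tx)] + 1L else
      tx$end[-1L] + 1L
    ge <- if (tx$strand[1] == "+") tx$start[-1L] - 1L else
      tx$start[-nrow(tx)] - 1L
    data.frame(gene_id = tx$gene_id[1], chrom = tx$chrom[1],
               start = gs, end = ge, strand = tx$strand[1],
               tx_intron = seq_len(nrow(tx) - 1L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(data.frame())
  out <- out[out$end >= out$start, ]
  out <- out[!duplicated(out[c("gene_id", "start", "end")]), ]
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

sample_sheet <- function(groups) {
  data.frame(
    sample_id = unlist(lapply(names(groups), function(g)
      sprintf("%s_%02d", g, seq_len(groups[[g]])))),
    group = rep(names(groups), times = as.integer(groups)),
    stringsAsFactors = FALSE)
}

# canonical linear junction table of a gene set: one row per unique
# consecutive exon pair, named lin|<gene>|<up_end>-<dn_start> in genomic
# coordinates
linear_junctions <- function(annotation) {
  pieces <- lapply(split(annotation, annotation$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 2L) return(NULL)
    up <- tx[-nrow(tx), ]; dn <- tx[-1L, ]
    data.frame(gene_id = tx$gene_id[1], chrom = tx$chrom[1],
               strand = tx$strand[1],
               up_start = up$start, up_end = up$end,
               dn_start = dn$start, dn_end = dn$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(data.frame())
  out <- out[!duplicated(out[c("gene_id", "up_end", "dn_start")]), ]
  out$junction_id <- sprintf("lin|%s|%d-%d", out$gene_id, out$up_end,
                             out$dn_start)
  rownames(out) <- NULL
  out
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) as.integer(stats::rpois(n, mu))
  else as.integer(stats::rnbinom(n, mu = mu, size = 1 / dispersion))
}

#' Simulate cohort count matrices
#'
#' Draws per-sample library-size factors (log-normal, sigma 0.3), then
#' negative-binomial gene, linear-junction, and back-splice junction counts
#' around the gene/circRNA base means fixed at annotation time. CircRNA count
#' means in the suppressed group are multiplied by the spec's
#' `suppression_factor` before sampling; the planted specific circRNAs are
#' multiplied by `specific_fold` in the focal cohort only.
#'
#' @param sim a `circ_sim` from [generate_annotation()].
#' @param groups named sample counts per group; defaults to the spec's.
#' @param suppressed_group group whose circ counts are suppressed, or `NULL`
#'   for none (control cohorts); must be one of `names(groups)`.
#' @param focal logical; `TRUE` for the focal cohort (specific circRNAs
#'   elevated), `FALSE` for a control cohort.
#' @param seed optional integer overriding the seed derived from the spec
#'   (use distinct seeds for control cohorts).
#' @return list with integer matrices `bsj` (circ_id x sample), `linear`
#'   (junction_id x sample), `gene` (gene_id x sample), and data.frame
#'   `samples` (sample_id, group, lib_factor).
#' @export
simulate_cohort_counts <- function(sim, groups = NULL, suppressed_group = NA,
                                   focal = TRUE, seed = NULL) {
  stopifnot(inherits(sim, "circ_sim"))
  spec <- sim$spec
  if (is.null(groups)) groups <- spec$n_samples_per_group
  if (length(suppressed_group) == 1L && is.na(suppressed_group))
    suppressed_group <- if (focal) spec$suppressed_group else NULL
  if (!is.null(suppressed_group) &&
      !suppressed_group %in% names(groups))
    stop("simulate_cohort_counts: unknown group label '", suppressed_group,
         "' in suppression assignment")
  if (is.null(seed)) seed <- derive_seed(spec$seed, 2L + !focal)
  with_rng(seed, {
    samples <- sample_sheet(groups)
    n <- nrow(samples)
    samples$lib_factor <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)
    suppressed <- if (is.null(suppressed_group)) rep(FALSE, n)
                  else samples$group == suppressed_group

    gmu <- sim$genes$base_mean
    gene_mat <- vapply(seq_len(n), function(j)
      rcounts(length(gmu), gmu * samples$lib_factor[j], spec$nb_dispersion),
      integer(length(gmu)))
    dimnames(gene_mat) <- list(sim$genes$gene_id, samples$sample_id)

    lj <- linear_junctions(sim$annotation)
    lmu <- gmu[match(lj$gene_id, sim$genes$gene_id)]
    lin_mat <- vapply(seq_len(n), function(j)
      rcounts(length(lmu), lmu * samples$lib_factor[j], spec$nb_dispersion),
      integer(length(lmu)))
    dimnames(lin_mat) <- list(lj$junction_id, samples$sample_id)

    tr <- sim$truth$circ_records
    if (nrow(tr) > 0) {
      cmu0 <- tr$base_mean
      if (focal && length(sim$truth$specific_ids) > 0)
        cmu0 <- cmu0 * ifelse(tr$specific, spec$specific_fold, 1)
      bsj_mat <- vapply(seq_len(n), function(j) {
        mu <- cmu0 * samples$lib_factor[j] *
          if (suppressed[j]) spec$suppression_factor else 1
        rcounts(length(mu), mu, spec$nb_dispersion)
      }, integer(nrow(tr)))
      dimnames(bsj_mat) <- list(tr$circ_id, samples$sample_id)
    } else {
      bsj_mat <- matrix(0L, 0, n, dimnames = list(NULL, samples$sample_id))
    }
    list(bsj = bsj_mat, linear = lin_mat, gene = gene_mat, samples = samples)
  })
}

#' Truth circRNAs as a confident-set table
#'
#' Formats the generator's truth records like the output of
#' [annotate_candidates()], so the junction reference and all downstream
#' stages can run directly from truth.
#'
#' @param sim a `circ_sim`.
#' @return confident-set data.frame (see [annotate_candidates()]).
#' @export
truth_confident <- function(sim) {
  tr <- sim$truth$circ_records
  ex <- sim$annotation
  acc <- mapply(function(g, e) which(ex$gene_id == g & ex$exon_number == e)[1],
                tr$gene_id, tr$acceptor_exon)
  don <- mapply(function(g, e) which(ex$gene_id == g & ex$exon_number == e)[1],
                tr$gene_id, tr$donor_exon)
  data.frame(
    circ_id = tr$circ_id, gene_id = tr$gene_id,
    chrom = tr$chrom, start = tr$start, end = tr$end, strand = tr$strand,
    acceptor_exon = tr$acceptor_exon, donor_exon = tr$donor_exon,
    acceptor_start = ex$start[acc], acceptor_end = ex$end[acc],
    donor_start = ex$start[don], donor_end = ex$end[don],
    disc_start = 0L, disc_end = 0L,
    stringsAsFactors = FALSE)
}

#' Write the synthetic build to standard formats
#'
#' Genome as FASTA, annotation as GENCODE-dialect GTF (1-based inclusive),
#' repeats as BED6 (0-based half-open), truth set as a JSON sidecar.
#'
#' @param sim a `circ_sim`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             gtf = file.path(outdir, "annotation.gtf"),
             bed = file.path(outdir, "repeats.bed"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_gtf(sim$annotation, sim$genes, paths["gtf"])
  rep_df <- as.data.frame(sim$repeats)
  if (nrow(rep_df) > 0) {
    bed <- data.frame(rep_df$seqnames, rep_df$start - 1L, rep_df$end,
                      rep_df$name, 0L, rep_df$strand)
    utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else file.create(paths["bed"])
  jsonlite::write_json(
    list(circ_records = sim$truth$circ_records,
         specific_ids = sim$truth$specific_ids,
         suppressed_group = sim$truth$suppressed_group),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_gtf <- function(annotation, genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  for (g in seq_len(nrow(genes))) {
    gr <- genes[g, ]
    writeLines(sprintf(
      '%s\tcircscape_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
      gr$chrom, gr$start, gr$end, gr$strand, gr$gene_id), con)
    ex <- annotation[annotation$gene_id == gr$gene_id, ]
    ex <- ex[order(ex$start), ]
    writeLines(sprintf(
      '%s\tcircscape_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      gr$chrom, gr$start, gr$end, gr$strand, gr$gene_id,
      ex$transcript_id[1]), con)
    writeLines(sprintf(
      '%s\tcircscape_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number %d;',
      ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
      ex$exon_number), con)
  }
  invisible(path)
}

#' Write CIRI2-style prediction tables for each sample
#'
#' One TSV per sample in the CIRI2 header dialect (columns circRNA_ID, chr,
#' circRNA_start, circRNA_end, junction_reads, strand, circRNA_type). Truth
#' circRNAs with a nonzero back-splice count in a sample are reported for
#' that sample; optional noise rows are placed on blacklist contigs and at
#' unannotated positions so catalog filters have work to do.
#'
#' @param sim a `circ_sim`.
#' @param bsj back-splice count matrix from [simulate_cohort_counts()].
#' @param outdir output directory.
#' @param n_noise noise candidate rows per sample.
#' @return invisibly, named vector of file paths per sample.
#' @export
simulate_ciri2_tables <- function(sim, bsj, outdir, n_noise = 5L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tr <- sim$truth$circ_records
  paths <- stats::setNames(
    file.path(outdir, paste0(colnames(bsj), ".ciri2.tsv")), colnames(bsj))
  with_rng(derive_seed(sim$spec$seed, 4L), {
    for (s in colnames(bsj)) {
      keep <- bsj[, s] > 0
      df <- data.frame(
        circRNA_ID = rownames(bsj)[keep],
        chr = tr$chrom[keep],
        circRNA_start = tr$start[keep],
        circRNA_end = tr$end[keep],
        junction_reads = bsj[keep, s],
        strand = tr$strand[keep],
        circRNA_type = "exon", stringsAsFactors = FALSE)
      if (n_noise > 0) {
        noise_chr <- sample(c("chrM", "chrY", "KI270713.1", "chrS1"),
                            n_noise, replace = TRUE)
        st <- sample(1000:5000, n_noise)
        en <- st + sample(200:800, n_noise)
        noise <- data.frame(
          circRNA_ID = sprintf("%s:%d-%d", noise_chr, st, en),
          chr = noise_chr, circRNA_start = st, circRNA_end = en,
          junction_reads = sample(1:10, n_noise, replace = TRUE),
          strand = sample(c("+", "-"), n_noise, replace = TRUE),
          circRNA_type = "exon", stringsAsFactors = FALSE)
        df <- rbind(df, noise)
      }
      utils::write.table(df, paths[s], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  })
  invisible(paths)
}

#' Emit junction-spanning read pairs as SAM alignments
#'
#' For each junction contig and sample, exactly the counted number of read
#' pairs is written as primary alignment records spanning the junction
#' breakpoint with first mate reverse / second mate forward and MAPQ 60.
#' Optionally, labeled decoy records are added per class: `lowmapq` (MAPQ 5),
#' `secondary` (0x100 flag set), `wrong_orient` (first mate forward / second
#' reverse), `nonspanning` (placed away from the breakpoint). Decoy read
#' names carry a `decoy:<class>:` prefix so tests can assert that counters
#' ignore them.
#'
#' @param ref a `junction_reference` from [build_junction_reference()].
#' @param counts integer matrix (contig x sample); rows restricted to contigs
#'   present in `ref`.
#' @param outdir directory for per-sample SAM files.
#' @param read_len read length (nt); must be at least `2 * overhang`.
#' @param frag_len nominal fragment length (nt).
#' @param overhang minimum junction overhang the spanning mate guarantees.
#' @param decoys named integer vector of decoy pairs per class per sample
#'   (names among lowmapq, secondary, wrong_orient, nonspanning).
#' @param fastq also write the pairs as FASTQ (for external aligners).
#' @param seed integer seed.
#' @return invisibly, named vector of SAM paths per sample.
#' @export
simulate_junction_reads <- function(ref, counts, outdir, read_len = 75L,
                                    frag_len = 150L, overhang = 5L,
                                    decoys = c(lowmapq = 0L, secondary = 0L,
                                               wrong_orient = 0L,
                                               nonspanning = 0L),
                                    fastq = FALSE, seed = 99L) {
  stopifnot(inherits(ref, "junction_reference"))
  if (read_len < 2L * overhang)
    stop("simulate_junction_reads: read_len below the minimum spanning ",
         "overhang (need >= ", 2L * overhang, ")")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  contigs <- ref$contigs
  unknown <- setdiff(rownames(counts), contigs$name)
  if (length(unknown) > 0)
    stop("simulate_junction_reads: counted features absent from reference: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  dec <- c(lowmapq = 0L, secondary = 0L, wrong_orient = 0L, nonspanning = 0L)
  dec[names(decoys)] <- as.integer(decoys)
  paths <- stats::setNames(
    file.path(outdir, paste0(colnames(counts), ".sam")), colnames(counts))

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name, contigs$length))

  emit_pair <- function(qname, contig, clen, offset, mapq, flags_first_rev,
                        secondary, spanning, seqs) {
    if (spanning) {
      pos1 <- max(1L, min(offset - as.integer(floor(read_len / 2)) + 1L,
                          clen - read_len + 1L))
    } else {
      pos1 <- if (clen - read_len + 1L > offset + overhang)
        offset + overhang + 1L else 1L
      # ensure no overlap with the breakpoint window
      if (pos1 + read_len - 1L >= offset - overhang + 1L &&
          pos1 <= offset + overhang)
        pos1 <- max(1L, offset - overhang + 1L - read_len)
    }
    pos2 <- max(1L, pos1 - (frag_len - read_len))
    if (pos2 + read_len - 1L > clen) pos2 <- max(1L, clen - read_len + 1L)
    # keep both mates of a non-spanning pair clear of the breakpoint window
    if (!spanning) pos2 <- pos1
    f1 <- if (flags_first_rev) 83L else 99L     # paired,proper + strand bits
    f2 <- if (flags_first_rev) 163L else 147L
    if (secondary) { f1 <- f1 + 256L; f2 <- f2 + 256L }
    s1 <- substring(seqs, pos1, pos1 + read_len - 1L)
    s2 <- substring(seqs, pos2, pos2 + read_len - 1L)
    qual <- strrep("I", read_len)
    c(paste(qname, f1, contig, pos1, mapq, paste0(read_len, "M"), "=", pos2,
            -(pos1 - pos2 + read_len), s1, qual, sep = "\t"),
      paste(qname, f2, contig, pos2, mapq, paste0(read_len, "M"), "=", pos1,
            pos1 - pos2 + read_len, s2, qual, sep = "\t"))
  }

  with_rng(seed, {
    for (s in colnames(counts)) {
      lines <- vector("list", nrow(counts) + 4L)
      li <- 0L
      for (i in seq_len(nrow(counts))) {
        n_pairs <- counts[i, s]
        if (n_pairs == 0) next
        cinfo <- contigs[match(rownames(counts)[i], contigs$name), ]
        seqs <- as.character(ref$sequences[[cinfo$name]])
        recs <- unlist(lapply(seq_len(n_pairs), function(p)
          emit_pair(sprintf("frag:%s:%s:%d", cinfo$name, s, p),
                    cinfo$name, cinfo$length, cinfo$offset, 60L,
                    TRUE, FALSE, TRUE, seqs)))
        li <- li + 1L; lines[[li]] <- recs
      }
      # decoys on random counted contigs
      counted <- rownames(counts)[counts[, s] > 0]
      if (length(counted) > 0) {
        for (cls in names(dec)) {
          if (dec[[cls]] == 0) next
          recs <- unlist(lapply(seq_len(dec[[cls]]), function(p) {
            nm <- sample(counted, 1L)
            cinfo <- contigs[match(nm, contigs$name), ]
            seqs <- as.character(ref$sequences[[nm]])
            emit_pair(sprintf("decoy:%s:%s:%d", cls, s, p), nm, cinfo$length,
                      cinfo$offset,
                      mapq = if (cls == "lowmapq") 5L else 60L,
                      flags_first_rev = cls != "wrong_orient",
                      secondary = cls == "secondary",
                      spanning = cls != "nonspanning", seqs)
          }))
          li <- li + 1L; lines[[li]] <- recs
        }
      }
      body <- unlist(lines[seq_len(li)])
      writeLines(c(header, body), paths[s])
      if (fastq) write_pair_fastq(body, sub("\\.sam$", "", paths[s]))
    }
  })
  invisible(paths)
}

# export SAM body lines as a FASTQ pair (reverse-flag reads are
# reverse-complemented back to read orientation)
write_pair_fastq <- function(body, prefix) {
  if (length(body) == 0) {
    file.create(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"))
    return(invisible(NULL))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  flag <- as.integer(f[, 2])
  seqs <- f[, 10]
  rev_idx <- bitwAnd(flag, 16L) > 0
  seqs[rev_idx] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[rev_idx])))
  is_first <- bitwAnd(flag, 64L) > 0
  for (mate in 1:2) {
    sel <- if (mate == 1) is_first else !is_first
    out <- paste0("@", f[sel, 1], "/", mate, "\n", seqs[sel], "\n+\n",
                  strrep("I", nchar(seqs[sel])))
    writeLines(out, sprintf("%s_%d.fastq", prefix, mate))
  }
  invisible(NULL)
}
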