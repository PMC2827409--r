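#' Simulate one BAC: reference, annotation, bias, shotgun library, draft
#'
#' Bundles the synthetic-data generators with defaults that emulate the
#' assay's study material: ~165 kb templates, >= 8-fold redundancy from
#' 3-5 kb insert plasmid subclones, vertebrate-like repeat densities, and a
#' handful of low-viability ("cloning-poisonous") regions that depress
#' subclone recovery and seed gaps.
#'
#' @param length Template length (bp).
#' @param gc_target Background GC fraction.
#' @param redundancy,read_len,insert_mean,insert_sd Shotgun parameters.
#' @param n_bias Number of low-viability regions.
#' @param bias_length Length range (bp) of the bias regions.
#' @param viability Subclone viability inside bias regions.
#' @param host `"standard"` or `"copy_control"`.
#' @param copy_control_rescue Rescue fraction under the copy-control host.
#' @param simple_in_bias Fraction of each bias region's bases planted as
#'   simple-repeat tracts (models the repeat character of gap-prone DNA).
#' @param repeat_densities Passed to [repeat_layout()]; NULL plants no
#'   interspersed/simple repeats outside bias regions.
#' @param gc_islands Passed to [generate_reference()].
#' @param min_contig,min_depth,shuffle,chimera Passed to [build_draft()].
#' @param id,species,region Metadata.
#' @param seed Integer seed; the whole BAC is reproducible from it.
#' @return List: `ref`, `annotation`, `bias`, `pairs`, `draft`.
#' @export
simulate_bac <- function(length = 165000, gc_target = 0.4, redundancy = 8,
                         read_len = 800, insert_mean = 4000, insert_sd = 400,
                         n_bias = 3, bias_length = c(500, 4000),
                         viability = 0.1, host = "standard",
                         copy_control_rescue = 1, simple_in_bias = 0,
                         repeat_densities = NULL, gc_islands = NULL,
                         min_contig = 2000, min_depth = 1, shuffle = FALSE,
                         chimera = FALSE, id = "bac1", species = "synthetic",
                         region = "synthetic", seed = NULL) {
  with_seed_if(seed, {
    regions <- if (n_bias > 0) {
      lens <- sample(bias_length[1]:bias_length[2], n_bias, replace = TRUE)
      starts <- .place_intervals(length, lens, rep(NA_integer_, n_bias),
                                 label = "bias region")
      data.frame(start = starts, end = starts + lens, viability = viability)
    } else {
      data.frame(start = integer(0), end = integer(0), viability = numeric(0))
    }
    regions <- regions[order(regions$start), , drop = FALSE]

    repeats <- if (!is.null(repeat_densities)) {
      repeat_layout(length, densities = repeat_densities)
    } else NULL
    if (simple_in_bias > 0 && nrow(regions) > 0) {
      planted <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
        rlen <- regions$end[i] - regions$start[i]
        tract <- 40L
        k <- max(1L, floor(simple_in_bias * rlen / tract))
        pitch <- rlen / k
        starts <- regions$start[i] + floor((seq_len(k) - 1) * pitch)
        motifs <- vapply(seq_len(k), function(j) sample(.SIMPLE_MOTIFS[[sample(1:2, 1)]], 1),
                         character(1))
        data.frame(class = "Simple", length = pmin(tract, regions$end[i] - starts),
                   start = as.integer(starts), motif = motifs,
                   stringsAsFactors = FALSE)
      }))
      repeats <- rbind(planted, repeats)
    }

    gen <- generate_reference(length, gc_target = gc_target, repeats = repeats,
                              gc_islands = gc_islands, id = id,
                              species = species, region = region)
    bias <- bias_model(regions, host = host,
                       copy_control_rescue = copy_control_rescue)
    pairs <- simulate_shotgun(gen$reference, redundancy = redundancy,
                              read_len = read_len, insert_mean = insert_mean,
                              insert_sd = insert_sd, bias = bias)
    draft <- build_draft(gen$reference, pairs, min_contig = min_contig,
                         min_depth = min_depth, shuffle = shuffle,
                         chimera = chimera, annotation = gen$annotation,
                         bias = bias)
    list(ref = gen$reference, annotation = gen$annotation, bias = bias,
         pairs = pairs, draft = draft)
  })
}

#' Run the finishing-effort assay on one assembly
#'
#' Maps the draft contigs onto the finished reference, catalogues and
#' classifies gaps, scores redundancy variation, and verifies the
#' base-conservation identity (placed contig bases + internal gap bases +
#' terminal gap bases == reference length); a violation stops the run.
#'
#' @param ref A `finished_sequence`.
#' @param draft A `draft_assembly` (or `data.frame(contig_id, seq)`).
#' @param pairs Optional `read_pairs` in reference coordinates; when NULL,
#'   the draft's contig-coordinate placements are lifted through the map.
#' @param annotation Optional repeat annotation (enables the composition
#'   profile).
#' @param rule A [capture_rule()].
#' @param k,min_block Alignment parameters (see [align_contigs()]).
#' @param window Redundancy window (see [variation_score()]).
#' @param insert_mean,insert_sd Library statistics when `pairs` is a bare
#'   `data.frame`.
#' @return List: `map`, `gaps` (classified), `stats`, `profile`
#'   (`summary_cv`, `score`), `composition` (or NULL), `conservation`.
#' @export
assay_bac <- function(ref, draft, pairs = NULL, annotation = NULL,
                      rule = capture_rule(), k = 31, min_block = 200,
                      window = 2000, insert_mean = NULL, insert_sd = NULL) {
  aln <- align_contigs(draft, ref, k = k, min_block = min_block)
  ids <- if (inherits(draft, "draft_assembly")) draft$contigs$contig_id else unique(aln$contig_id)
  map <- resolve_map(aln, ref$length, contig_ids = ids, sequence_id = ref$id)
  gaps <- call_gaps(map)

  if (is.null(pairs)) {
    if (!inherits(draft, "draft_assembly")) {
      stopf("either reference-coordinate pairs or a draft with placements is required")
    }
    pairs_df <- lift_placements(draft$placements, map)
    insert_mean <- insert_mean %||% draft$library$insert_mean
    insert_sd <- insert_sd %||% draft$library$insert_sd
  } else {
    pairs_df <- pairs
  }
  gaps <- classify_gaps(gaps, pairs_df, rule = rule,
                        insert_mean = insert_mean, insert_sd = insert_sd)

  placed <- sum(map$placements$end - map$placements$start)
  gap_bases <- sum(gaps$size)
  if (placed + gap_bases != ref$length) {
    stopf("conservation violated for %s: contigs (%d) + gaps (%d) != length (%d)",
          ref$id, placed, gap_bases, ref$length)
  }

  profile <- .bac_variation(draft, window = window)
  comp <- if (!is.null(annotation)) composition_profile(ref, annotation, gaps) else NULL

  list(map = map, gaps = gaps,
       stats = gap_stats(gaps, ref$length / 1e6, unit = ref$id),
       profile = profile, composition = comp,
       conservation = c(placed = placed, gap_bases = gap_bases,
                        length = ref$length))
}

# Pool windowed depth CVs across a draft's contigs and score the assembly.
.bac_variation <- function(draft, window = 2000, thresholds = c(0.35, 0.55, 0.80)) {
  if (!inherits(draft, "draft_assembly")) {
    return(list(summary_cv = NA_real_, score = NA_character_))
  }
  cvs <- unlist(lapply(seq_len(nrow(draft$contigs)), function(i) {
    cid <- draft$contigs$contig_id[i]
    prof <- depth_profile(draft$placements, draft$contigs$length[i], cid)
    variation_score(prof, window = window, thresholds = thresholds)$window_cv$cv
  }))
  summary_cv <- stats::quantile(cvs, 0.9, names = FALSE, type = 7)
  lev <- c("-", "+", "++", "++++")
  list(summary_cv = summary_cv,
       score = lev[1L + findInterval(summary_cv, thresholds, left.open = TRUE)])
}

#' Simulate and assay a cohort of BACs end to end
#'
#' @param n_bacs Number of BACs.
#' @param species,region Per-BAC labels (recycled).
#' @param seed Integer seed; per-BAC sub-seeds are drawn from it.
#' @param shuffle Shuffle contig order/orientation in each draft.
#' @param reps Bootstrap replicates in the summary.
#' @param ... Passed to [simulate_bac()].
#' @return List: `manifest`, `per_bac`, `gaps` (with `bac_id`), `summary`
#'   (by the first grouping with > 1 level, else by species), `results`
#'   (per-BAC assay outputs).
#' @export
run_synthetic_assay <- function(n_bacs, species = "synthetic",
                                region = "synthetic", seed = 1,
                                shuffle = TRUE, reps = 200, ...) {
  species <- rep_len(species, n_bacs)
  region <- rep_len(region, n_bacs)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_bacs))
  results <- vector("list", n_bacs)
  per_bac <- vector("list", n_bacs)
  gaps <- vector("list", n_bacs)
  for (i in seq_len(n_bacs)) {
    id <- sprintf("bac%03d", i)
    sim <- simulate_bac(id = id, species = species[i], region = region[i],
                        shuffle = shuffle, seed = seeds[i], ...)
    res <- assay_bac(sim$ref, sim$draft, pairs = sim$pairs,
                     annotation = sim$annotation)
    res$sim <- sim
    g <- res$gaps
    g$bac_id <- rep(id, nrow(g))
    gaps[[i]] <- g
    per_bac[[i]] <- data.frame(
      bac_id = id, species = species[i], region = region[i],
      finished_length = sim$ref$length,
      n_contigs = nrow(sim$draft$contigs),
      n_gaps = sum(g$kind == "internal"),
      n_uncaptured = sum(g$kind == "internal" & g$status == "uncaptured"),
      summary_cv = res$profile$summary_cv, score = res$profile$score,
      stringsAsFactors = FALSE)
    results[[i]] <- res
  }
  per_bac <- do.call(rbind, c(per_bac, list(make.row.names = FALSE)))
  gaps <- do.call(rbind, c(gaps, list(make.row.names = FALSE)))
  manifest <- per_bac[, c("bac_id", "species", "region", "finished_length")]
  summ <- summarize_assay(per_bac, gaps,
                          group_by = if (length(unique(region)) > 1) "region" else "species",
                          reps = reps, seed = seed)
  list(manifest = manifest, per_bac = per_bac, gaps = gaps, summary = summ,
       results = results)
}

#' Write the standard report files for an assay run
#'
#' Emits `gaps.bed`, `gaps.tsv`, `per_bac.tsv`, `summary_by_species.tsv`
#' and `summary_by_region.tsv` (full precision, with `*_rounded.tsv`
#' presentation copies at one decimal), plus `run.log`.
#'
#' @param run Result of [run_synthetic_assay()].
#' @param outdir Output directory (created if needed).
#' @param seed Seed echoed into the log.
#' @export
write_assay_outputs <- function(run, outdir, seed = NA) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_gaps_bed(run$gaps, p("gaps.bed"))
  write_gaps_tsv(run$gaps, p("gaps.tsv"))
  utils::write.table(run$per_bac, p("per_bac.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (grp in c("species", "region")) {
    s <- summarize_assay(run$per_bac, run$gaps, group_by = grp,
                         reps = 200, seed = 1)
    utils::write.table(s, p(sprintf("summary_by_%s.tsv", grp)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(round_report(s), p(sprintf("summary_by_%s_rounded.tsv", grp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tot <- aggregate_manifest(run$manifest)
  writeLines(c(
    sprintf("finishassay run: %d assemblies, %.2f Mb, seed %s",
            tot$n_bacs, tot$total_mb, as.character(seed)),
    sprintf("%s: %d contigs, %d internal gaps, %d uncaptured, score %s",
            run$per_bac$bac_id, run$per_bac$n_contigs, run$per_bac$n_gaps,
            run$per_bac$n_uncaptured, run$per_bac$score)),
    p("run.log"))
  invisible(outdir)
}
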