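## End-to-end pipeline: records -> alignment -> distances -> (P)NJ tree with
## bootstrap -> rooted Newick.  Every artifact is written to the output
## directory; identical config + seed reproduces byte-identical artifacts.

#' Pipeline configuration
#'
#' @param input Path to a Vienna-style record file.
#' @param output_dir Output directory (created if missing).
#' @param matrix_file Optional scoring-matrix file ([read_scoring_matrix()]);
#'   default is [default_scoring_matrix()].
#' @param model `"default_jc"`, `"estimate"` (fit by [estimate_gtr()] on the
#'   alignment), or a path to a model file ([read_gtr_model()]).
#' @param method `"nj"`, `"pnj"` (automatic profiling), or `"pnj-manual"`
#'   (profiles from `profile_definition`).  Supplying `profile_definition`
#'   implies `"pnj-manual"`.
#' @param B Bootstrap replicates (default 100; `0` skips bootstrap
#'   annotation for `"nj"`; `"pnj"` requires `B >= 1`).
#' @param support_threshold Percent support for automatic profiling.
#' @param outgroup Optional character vector of outgroup taxon ids.
#' @param profile_definition Optional profile-definition file path.
#' @param seed Single integer seed governing all stochastic stages (each
#'   stage derives its own stream as `seed + stage offset`).
#' @return A `ss_pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir, matrix_file = NULL,
                            model = "default_jc", method = c("nj", "pnj", "pnj-manual"),
                            B = 100, support_threshold = 70, outgroup = NULL,
                            profile_definition = NULL, seed = 1) {
  method <- match.arg(method)
  if (!is.null(profile_definition)) method <- "pnj-manual"
  if (method == "pnj" && B < 1) stop("method 'pnj' requires B >= 1")
  structure(list(input = input, output_dir = output_dir,
                 matrix_file = matrix_file, model = model, method = method,
                 B = B, support_threshold = support_threshold,
                 outgroup = outgroup, profile_definition = profile_definition,
                 seed = as.integer(seed)),
            class = "ss_pipeline_config")
}

#' Run the sequence-structure phylogenetics pipeline
#'
#' Stages, in order: read and validate records; encode; multiple
#' sequence-structure alignment; substitution model (bundled 12-state JC,
#' file, or estimated); ML distance matrix (written as square PHYLIP); tree
#' building by NJ (with bootstrap support annotation when `B >= 1`),
#' automatic-profile PNJ, or manual-profile NJ; optional outgroup rooting.
#' Per-stage counts, warnings and timings go to `log.txt`; artifacts and
#' their md5 sums are listed in `MANIFEST` (marked `INCOMPLETE` if a stage
#' aborts, with partial outputs retained).  Timing lines live only in the
#' log, so artifact files are byte-reproducible given config + seed.
#'
#' @param config A [pipeline_config()].
#' @return List with the main objects (`alignment`, `model`, `distances`,
#'   `tree`, `rooted`) and `files` (named vector of artifact paths).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "log.txt")
  manifest_path <- file.path(config$output_dir, "MANIFEST")
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                             append = TRUE)
  cat("", file = log_path)
  files <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        .write_manifest(manifest_path, files, incomplete = TRUE)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        logln("[%s] warning: %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    logln("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  records <- stage("read", {
    if (!file.exists(config$input))
      stop(sprintf("input file not found: %s", config$input))
    r <- read_vienna(config$input)
    if (length(r) < 3L) stop("need at least 3 records")
    logln("[read] %d records", length(r))
    r
  })
  encs <- stage("encode", encode_records(records))
  scoring <- stage("scoring", {
    if (is.null(config$matrix_file)) default_scoring_matrix()
    else read_scoring_matrix(config$matrix_file)
  })
  aln <- stage("align", {
    a <- align_msa(encs, scoring)
    f <- file.path(config$output_dir, "alignment.fasta")
    write_alignment_fasta(a, f)
    fs <- file.path(config$output_dir, "alignment.seq.fasta")
    fb <- file.path(config$output_dir, "alignment.struct")
    write_alignment_split(a, fs, fb)
    files <- c(files, f, fs, fb)
    logln("[align] %d rows x %d columns", length(a$ids), a$L)
    a
  })
  model <- stage("model", {
    m <- if (identical(config$model, "default_jc")) jc12_model()
         else if (identical(config$model, "estimate")) estimate_gtr(aln)
         else read_gtr_model(config$model)
    f <- file.path(config$output_dir, "model.txt")
    write_gtr_model(m, f)
    files <- c(files, f)
    m
  })
  dists <- stage("distances", {
    d <- distance_matrix(aln, model)
    f <- file.path(config$output_dir, "distances.phy")
    write_phylip(d, f)
    files <- c(files, f)
    if (any(d$saturated)) logln("[distances] %d saturated pairs",
                                sum(d$saturated) / 2)
    d
  })
  tree <- stage("tree", {
    tr <- switch(config$method,
      nj = {
        t0 <- neighbor_joining(dists)
        if (config$B >= 1 && length(aln$ids) >= 4L)
          bootstrap_support(aln, model, B = config$B,
                            seed = config$seed + 101L)$tree
        else t0
      },
      pnj = profile_neighbor_joining(aln, model,
                                     support_threshold = config$support_threshold,
                                     B = config$B, seed = config$seed + 201L),
      `pnj-manual` = {
        defn <- read_profile_definition(config$profile_definition)
        ent <- build_profiles(aln, defn)$entities
        d <- .profile_dist_matrix(ent, model)
        t0 <- neighbor_joining(d)
        full_d <- distance_matrix(aln, model)
        for (e in ent) {
          if (length(e$members) < 2L) next
          t0 <- .splice_at_tip(t0, sort(e$members)[1],
                               .member_subtree(full_d, e$members))
        }
        t0
      })
    f <- file.path(config$output_dir, "tree_unrooted.nwk")
    write_newick(tr, f)
    files <- c(files, f)
    tr
  })
  rooted <- NULL
  if (!is.null(config$outgroup)) {
    rooted <- stage("root", {
      rt <- root_with_outgroup(tree, config$outgroup)
      f <- file.path(config$output_dir, "tree_rooted.nwk")
      write_newick(rt, f)
      files <- c(files, f)
      rt
    })
  }
  .write_manifest(manifest_path, files, incomplete = FALSE)
  list(alignment = aln, model = model, distances = dists, tree = tree,
       rooted = rooted,
       files = setNames(files, basename(files)))
}

.write_manifest <- function(path, files, incomplete) {
  lines <- character(0)
  if (incomplete) lines <- "# INCOMPLETE: a pipeline stage failed"
  if (length(files)) {
    sums <- tools::md5sum(files)
    lines <- c(lines, sprintf("%s  %s", sums, basename(files)))
  }
  writeLines(lines, path)
  invisible(path)
}
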