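#' Configure an end-to-end pipeline run
#'
#' Collects every stage parameter, the input/output locations and the
#' stage enable flags for [runPipeline()]. Inputs are checked up front
#' (fail fast): each enabled stage must be able to resolve its inputs
#' either from files or from an earlier enabled stage.
#'
#' @param outdir output directory (created if absent).
#' @param seed master seed for every source of randomness.
#' @param stages character subset of `"simulate"`, `"preprocess"`,
#'   `"cluster"`, `"diffmeth"`, `"aberration"`, `"cohort_stats"`, in
#'   pipeline order.
#' @param cohort a [cohortConfig()] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @param beta_path,manifest_path,mutation_path,clinical_path input files,
#'   required for stages whose producer stage is disabled.
#' @param normal_ids sample ids forming the normal panel when reading from
#'   files (ignored when simulating).
#' @param rank,fraction preprocessing parameters (see
#'   [preprocessMethylation()]).
#' @param k,distance,linkage clustering parameters.
#' @param diff_groups list with integer vectors `A` and `B`: the cluster
#'   labels compared by the differential stage (default clusters 1+2
#'   versus 3+4).
#' @param p_threshold,fc_threshold differential thresholds.
#' @param q,t_grid,sigma_floor aberration-stage parameters.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(outdir,
                           seed = 1L,
                           stages = c("simulate", "preprocess", "cluster",
                                      "diffmeth", "aberration",
                                      "cohort_stats"),
                           cohort = cohortConfig(seed = seed),
                           beta_path = NULL, manifest_path = NULL,
                           mutation_path = NULL, clinical_path = NULL,
                           normal_ids = character(),
                           rank = 5L, fraction = 0.01,
                           k = 4L, distance = "euclidean",
                           linkage = "ward.D2",
                           diff_groups = list(A = c(1L, 2L), B = c(3L, 4L)),
                           p_threshold = 1e-8, fc_threshold = 2,
                           q = 0.05, t_grid = seq(0.5, 10, by = 0.05),
                           sigma_floor = 1e-8) {
    all_stages <- c("simulate", "preprocess", "cluster", "diffmeth",
                    "aberration", "cohort_stats")
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
    cfg <- list(outdir = outdir, seed = as.integer(seed),
                stages = intersect(all_stages, stages), cohort = cohort,
                beta_path = beta_path, manifest_path = manifest_path,
                mutation_path = mutation_path,
                clinical_path = clinical_path, normal_ids = normal_ids,
                rank = rank, fraction = fraction, k = as.integer(k),
                distance = distance, linkage = linkage,
                diff_groups = diff_groups, p_threshold = p_threshold,
                fc_threshold = fc_threshold, q = q, t_grid = t_grid,
                sigma_floor = sigma_floor)
    .validatePipelineConfig(cfg)
    structure(cfg, class = "PipelineConfig")
}

.validatePipelineConfig <- function(cfg) {
    simulated <- "simulate" %in% cfg$stages
    needBeta <- any(c("preprocess", "cluster", "diffmeth", "aberration")
                    %in% cfg$stages)
    if (needBeta && !simulated) {
        if (is.null(cfg$beta_path) || is.null(cfg$manifest_path))
            stop("beta_path and manifest_path are required when the ",
                 "simulate stage is disabled")
        for (p in c(cfg$beta_path, cfg$manifest_path))
            if (!file.exists(p)) stop("input not found: ", p)
    }
    if ("cohort_stats" %in% cfg$stages && !simulated) {
        if (is.null(cfg$mutation_path) || is.null(cfg$clinical_path))
            stop("mutation_path and clinical_path are required when the ",
                 "simulate stage is disabled")
        for (p in c(cfg$mutation_path, cfg$clinical_path))
            if (!file.exists(p)) stop("input not found: ", p)
    }
    invisible(TRUE)
}

#' Run the methylation analysis pipeline
#'
#' Executes the enabled stages in order — simulate, preprocess, cluster,
#' differential probes, aberration model, cohort statistics — writing
#' every output as plain text under `config$outdir` and returning a run
#' manifest with the parameters actually used, a warning tally and an md5
#' checksum per output file. Identical configuration and seed reproduce
#' identical checksums.
#'
#' @param config a [pipelineConfig()].
#' @return The run manifest (list), invisibly; also written as
#'   `run_manifest.json` in `outdir`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    .validatePipelineConfig(config)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character()
    warnings_log <- character()
    note <- function(path) outputs <<- c(outputs, path)
    run <- function(stage, expr) {
        withCallingHandlers(
            tryCatch(expr, error = function(e)
                stop("stage '", stage, "' failed: ", conditionMessage(e),
                     call. = FALSE)),
            warning = function(w) {
                warnings_log <<- c(warnings_log,
                                   paste0(stage, ": ",
                                          conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
    }
    out <- function(name) file.path(config$outdir, name)
    me <- mutations <- clinical <- truth <- NULL

    if ("simulate" %in% config$stages) {
        run("simulate", {
            cc <- config$cohort
            cc$seed <- config$seed
            sim <- simulateCohort(do.call(cohortConfig,
                                          unclass(cc)))
            me <- sim$experiment
            mutations <- sim$mutations
            clinical <- sim$clinical
            truth <- sim$truth
            note(writeBetaMatrix(me, out("beta.tsv")))
            note(writeProbeAnnotation(sim$annotation, out("manifest.csv")))
            note(writeMutationTable(mutations, out("mutations.tsv")))
            note(writeClinicalTable(clinical, out("clinical.tsv")))
            write_json(list(cluster = as.list(truth$cluster),
                            aberrant = truth$aberrant,
                            clip_count = truth$clip_count),
                       out("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
            note(out("ground_truth.json"))
        })
    }
    if (is.null(me) && !is.null(config$beta_path))
        me <- readMethylationExperiment(config$beta_path,
                                        config$manifest_path,
                                        config$normal_ids)
    pp <- NULL
    if ("preprocess" %in% config$stages) {
        run("preprocess", {
            pp <- preprocessMethylation(me, rank = config$rank,
                                         fraction = config$fraction)
            writeLines(metadata(pp$reduced)$selected_probes,
                       out("selected_probes.txt"))
            note(out("selected_probes.txt"))
            note(writeBetaMatrix(pp$complete, out("beta_imputed.tsv")))
        })
    }
    clustering <- NULL
    if ("cluster" %in% config$stages) {
        run("cluster", {
            if (is.null(pp)) stop("preprocess stage output is required")
            clustering <- clusterMethylation(pp$reduced, k = config$k,
                                              distance = config$distance,
                                              linkage = config$linkage)
            lab <- clusterLabels(clustering)
            utils::write.table(
                data.frame(sample_id = names(lab), cluster = unname(lab)),
                out("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
            note(out("clusters.tsv"))
            note(writeDendrogram(clustering, out("dendrogram.nwk")))
        })
    }
    if ("diffmeth" %in% config$stages) {
        run("diffmeth", {
            if (is.null(clustering)) stop("cluster stage output is required")
            lab <- clusterLabels(clustering)
            ga <- names(lab)[lab %in% config$diff_groups$A]
            gb <- names(lab)[lab %in% config$diff_groups$B]
            dp <- differentialProbes(pp$reduced, ga, gb,
                                     p_threshold = config$p_threshold,
                                     fc_threshold = config$fc_threshold)
            utils::write.table(as.data.frame(dp), out("diff_probes.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            note(out("diff_probes.tsv"))
            gs <- summarizeGenes(dp, probeInfo(pp$reduced))
            utils::write.table(as.data.frame(gs), out("gene_summary.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            note(out("gene_summary.tsv"))
        })
    }
    if ("aberration" %in% config$stages) {
        run("aberration", {
            src <- if (!is.null(pp)) pp$complete else me
            ab <- callMethylationAberrations(src, q = config$q,
                                             t_grid = config$t_grid,
                                             sigma_floor =
                                                 config$sigma_floor)
            utils::write.table(
                data.frame(sample_id = rownames(ab@z),
                           ab@z, check.names = FALSE),
                out("zscores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
            note(out("zscores.tsv"))
            utils::write.table(aberrationCalls(ab),
                               out("aberration_calls.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            note(out("aberration_calls.tsv"))
            utils::write.table(ab@fdrCurve, out("fdr_curve.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            note(out("fdr_curve.tsv"))
        })
    }
    if ("cohort_stats" %in% config$stages) {
        run("cohort_stats", {
            if (is.null(mutations) && !is.null(config$mutation_path))
                mutations <- readMutationTable(config$mutation_path)
            if (is.null(clinical) && !is.null(config$clinical_path))
                clinical <- readClinicalTable(config$clinical_path)
            lab <- if (!is.null(clustering))
                clusterLabels(clustering)
            else setNames(clinical$cluster_truth, clinical$sample_id)
            grouping <- setNames(as.character(lab), names(lab))
            stats <- list()
            selectors <- unique(mutations$gene[is.na(mutations$pathway)])
            for (g in selectors)
                stats$frequency[[g]] <-
                    mutationFrequency(mutations, grouping, genes = g)
            pws <- unique(na.omit(mutations$pathway))
            for (pw in pws)
                stats$frequency[[pw]] <-
                    mutationFrequency(mutations, grouping, pathway = pw)
            cl <- clinical[match(names(grouping), clinical$sample_id), ]
            groups <- sort(unique(grouping))
            if (length(groups) >= 2L) {
                g12 <- grouping %in% groups[1:2]
                stats$logrank_first_two <- logrankTest(
                    cl$os_months[g12], cl$event[g12], grouping[g12])
            }
            stats$km <- lapply(kmEstimate(cl$os_months, cl$event,
                                          grouping), as.list)
            write_json(stats, out("cohort_stats.json"), auto_unbox = TRUE,
                       digits = NA)
            note(out("cohort_stats.json"))
        })
    }
    manifest <- list(
        seed = config$seed,
        stages = config$stages,
        parameters = config[c("rank", "fraction", "k", "distance",
                              "linkage", "p_threshold", "fc_threshold",
                              "q", "sigma_floor")],
        warnings = warnings_log,
        n_warnings = length(warnings_log),
        outputs = lapply(outputs, function(p)
            list(file = basename(p), md5 = unname(md5sum(p)))))
    write_json(manifest, file.path(config$outdir, "run_manifest.json"),
               auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
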