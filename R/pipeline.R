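## End-to-end pipeline: score/mask -> screen -> classify -> condense ->
## network -> date -> summarize, with reproducible TSV artifacts.

#' Pipeline configuration
#'
#' Read/write a pipeline configuration as a DCF (Debian-control-format) text
#' file: one \code{Field: value} pair per line. Recognised fields:
#' \code{profiles} (TSV path, required), \code{definitions} (path or
#' \code{"m9ab"}/\code{"f1c"}), \code{reference} (FASTA path, optional),
#' \code{gene_table} (TSV path, optional), \code{clock} (\code{"hvsi"} or
#' \code{"linear:RATE"}), \code{exclude_sites} (comma-separated),
#' \code{epsilon}, \code{weight}, \code{near_match_k}, \code{seed},
#' \code{out_dir}. Configurations round-trip through save/load.
#'
#' @param path DCF file path.
#' @return a named list of class \code{mt_pipeconfig}.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config not found: ", path)
  dcf <- read.dcf(path)
  cfg <- as.list(dcf[1, ])
  pipeline_config(cfg)
}

#' @rdname load_pipeline_config
#' @param cfg named list of fields (see above).
#' @export
pipeline_config <- function(cfg) {
  defaults <- list(definitions = "m9ab", clock = "hvsi",
                   exclude_sites = "11778", epsilon = "0", weight = "10",
                   near_match_k = "1", seed = "1", out_dir = ".")
  for (f in names(defaults)) cfg[[f]] <- cfg[[f]] %||% defaults[[f]]
  if (is.null(cfg$profiles)) stop("pipeline config needs a 'profiles' path")
  cfg$epsilon <- as.numeric(cfg$epsilon)
  cfg$weight <- as.numeric(cfg$weight)
  cfg$near_match_k <- as.integer(cfg$near_match_k)
  cfg$seed <- as.integer(cfg$seed)
  cfg$exclude_sites <- as.integer(strsplit(as.character(cfg$exclude_sites),
                                           "[,[:space:]]+")[[1]])
  structure(cfg, class = "mt_pipeconfig")
}

#' @rdname load_pipeline_config
#' @export
save_pipeline_config <- function(cfg, path) {
  flat <- lapply(unclass(cfg), function(v) paste(v, collapse = ","))
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}

parse_clock_string <- function(s) {
  if (identical(s, "hvsi")) return(hvsi_clock())
  if (grepl("^linear:", s)) return(linear_clock(as.numeric(sub("^linear:", "", s))))
  stop("unknown clock spec '", s, "' (use 'hvsi' or 'linear:RATE')")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes mask -> screen -> classify (with near-matching fallback) ->
#' condense -> median-joining network -> rho dating of the focal clade ->
#' frequency summary, writing every artifact as TSV/text under
#' \code{cfg$out_dir} together with a run log recording the configuration
#' hash and seed. Reruns with an identical configuration produce
#' byte-identical outputs.
#'
#' @param cfg an \code{mt_pipeconfig} (or path to one).
#' @return invisibly, a list with the in-memory stage results and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_pipeline_config(cfg)
  stopifnot(inherits(cfg, "mt_pipeconfig"))

  ## startup validation before any compute
  for (f in c("profiles", "reference", "gene_table")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) stop("missing ", f, " file: ", p)
  }
  if (!cfg$definitions %in% c("m9ab", "f1c") && !file.exists(cfg$definitions))
    stop("missing definitions file: ", cfg$definitions)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- if (!is.null(cfg$reference)) stage("reference", read_reference_fasta(cfg$reference))
  genes <- if (!is.null(cfg$gene_table)) stage("gene_table", read_gene_table(cfg$gene_table, ref))
  tree <- stage("definitions", load_definitions(cfg$definitions))
  clock <- stage("clock", parse_clock_string(cfg$clock))
  mask <- default_mask()

  profiles <- stage("read_profiles", read_profiles(cfg$profiles, ref = ref))
  masked <- stage("mask", lapply(profiles, apply_mask, mask = mask))
  screened <- stage("screen", vapply(masked, screen_m9ab_candidate, logical(1)))

  assignments <- stage("classify", {
    a <- lapply(masked, assign_haplogroup, tree = tree)
    classified <- Map(function(p, r) list(profile = p, label = r$label),
                      masked[vapply(a, function(r) r$status == "exact", logical(1))],
                      a[vapply(a, function(r) r$status == "exact", logical(1))])
    ## near-matching is the fallback for literature HVS-I profiles only;
    ## study samples carry coding information and keep their motif call
    if (length(classified)) {
      coding <- unlist(lapply(tree$nodes, function(nm) {
        pos <- if (length(tree$definers[[nm]]))
          parse_variant_token(sub("^@", "", tree$definers[[nm]]))$position
        else integer()
        pos[!is_control_position(pos)]
      }))
      for (i in which(vapply(a, function(r)
        r$status %in% c("screened_only", "unassigned"), logical(1)) &
          vapply(masked, function(p) p$source == "literature", logical(1)))) {
        nm <- near_match_assign(masked[[i]], classified, tree,
                                k = cfg$near_match_k, mask = mask,
                                coding_sites = coding)
        if (!nm$status %in% c("unassigned")) a[[i]] <- nm
      }
    }
    a
  })

  carriers <- screened | vapply(assignments, function(r)
    !is.na(r$label %||% NA), logical(1))
  net <- stage("network", {
    haps <- condense(masked[carriers], mask = mask)
    median_joining(haps, epsilon = cfg$epsilon,
                   weights = make_weights(colnames(haps$states),
                                          default = cfg$weight))
  })

  age <- stage("date", {
    focal <- focal_clade(tree)
    root_tokens <- cumulative_motif(tree, focal)
    root_tokens <- root_tokens[!startsWith(root_tokens, "@")]
    g <- genealogy_from_profiles(masked[carriers], root_tokens = root_tokens)
    date_clade(g, clock = clock, mask = mask,
               exclude_sites = cfg$exclude_sites, genes = genes, ref = ref)
  })

  freqs <- stage("summarize",
                 tabulate_frequencies(masked, assignments, tree))

  ## artifacts
  paths <- list(
    assignments = file.path(cfg$out_dir, "assignments.tsv"),
    network = file.path(cfg$out_dir, "network.txt"),
    ages = file.path(cfg$out_dir, "ages.tsv"),
    frequencies = file.path(cfg$out_dir, "frequencies.tsv"),
    log = file.path(cfg$out_dir, "run.log"))

  stage("write", {
    con <- file(paths$assignments, "wt", encoding = "UTF-8")
    writeLines("sample_id\tscreen\tlabel\tstatus\tdistance\tcontrol_region_only", con)
    for (i in seq_along(masked)) {
      r <- assignments[[i]]
      writeLines(paste(masked[[i]]$sample_id, as.integer(screened[i]),
                       ifelse(is.na(r$label %||% NA), "NA", r$label), r$status,
                       ifelse(is.na(r$distance_to_nearest), "NA",
                              r$distance_to_nearest),
                       as.integer(r$control_region_only), sep = "\t"), con)
    }
    close(con)
    export_network(net, paths$network)
    ky <- age_ky(age)
    writeLines(c("clade\tN\trho\tsigma\tT_ky\tdT_ky\tclock",
                 paste(focal_clade(tree), age$n, format(age$rho, digits = 6),
                       format(age$sigma, digits = 6),
                       sprintf("%.1f", ky[["T"]]), sprintf("%.1f", ky[["dT"]]),
                       age$clock_id, sep = "\t")),
               file.path(cfg$out_dir, "ages.tsv"))
    write_frequency_table(freqs, paths$frequencies)

    cfg_file <- file.path(cfg$out_dir, "config.dcf")
    save_pipeline_config(cfg, cfg_file)
    writeLines(c(paste0("mtlineage\t",
                        as.character(utils::packageVersion("mtlineage"))),
                 paste0("config_md5\t", unname(tools::md5sum(cfg_file))),
                 paste0("seed\t", cfg$seed)),
               paths$log)
  })

  invisible(list(config = cfg, profiles = masked, screened = screened,
                 assignments = assignments, network = net, age = age,
                 frequencies = freqs, paths = paths))
}
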