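## Reproducible runs: one dispatcher mapping command names onto the module
## functions, writing all artifacts plus a manifest under an output
## directory. The R functions are the primary interface; a thin Rscript
## wrapper over run() lives in inst/cli/propro.R for shell use.

#' Assemble a run configuration
#'
#' @param command one of `simulate-cell`, `simulate-population`,
#'   `bifurcation`, `quantify-movie`, `phospho-run`, `synth-phospho`,
#'   `synth-movie`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for every stochastic step of the command.
#' @param ... command parameters (see [run()]).
#' @return A `run_config` list.
#' @export
run_config <- function(command, out_dir, seed = 1, ...) {
  known <- c("simulate-cell", "simulate-population", "bifurcation",
             "quantify-movie", "phospho-run", "synth-phospho",
             "synth-movie")
  if (!command %in% known)
    stop("unknown command '", command, "'; expected one of: ",
         paste(known, collapse = ", "))
  structure(list(command = command, out_dir = out_dir,
                 seed = as.integer(seed), params = list(...)),
            class = "run_config")
}

write_manifest <- function(config, status) {
  ## in-memory objects handed to run() are echoed by class, not serialized
  echo <- lapply(config$params, function(p) {
    if (is.atomic(p) && length(p) <= 100) p
    else paste0("<", class(p)[1], ">")
  })
  manifest <- list(
    command = config$command,
    seed = config$seed,
    params = echo,
    package_version = as.character(utils::packageVersion("propro")),
    status = status,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Execute a configured run
#'
#' Dispatches to the module functions, writes every output as CSV/JSON
#' under `config$out_dir`, and always writes a `manifest.json` echoing the
#' configuration, seed and package version. Inputs are never mutated.
#'
#' Commands and their parameters:
#' \describe{
#'   \item{simulate-cell}{`f_plk1`, `cyca_cdk2_tot`, `horizon`; writes
#'     `trajectory.csv`.}
#'   \item{simulate-population}{`scenario` (preset name), `doses`,
#'     `n_cells`, `horizon`; writes `timing.csv` and `curves.csv`.}
#'   \item{bifurcation}{`f_plk1`, `pmin`, `pmax`, `n_grid`; writes
#'     `branches.csv` and `saddle_nodes.json`.}
#'   \item{quantify-movie}{`movie` (a [labeled_movie()]); writes
#'     `condensation.csv`.}
#'   \item{phospho-run}{`table` (a [phosphosite_table()]) plus
#'     [phospho_pipeline()] parameters; writes `interaction.csv` and one
#'     CSV per pairwise contrast.}
#'   \item{synth-phospho / synth-movie}{generator spec parameters; write
#'     the generated data and ground truth.}
#' }
#'
#' @param config a [run_config()].
#' @return Invisibly, the command's primary result object.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  result <- tryCatch({
    switch(config$command,
      "simulate-cell" = {
        pars <- default_params(
          f_plk1 = p$f_plk1 %||% 1,
          cyca_cdk2_tot = p$cyca_cdk2_tot %||% 4)
        tr <- simulate_cell(pars, horizon = p$horizon %||% 24)
        trajectory_frame(tr, file.path(config$out_dir, "trajectory.csv"))
        tr
      },
      "simulate-population" = {
        presets <- scenario_presets(n_cells = p$n_cells %||% 400)
        sc <- presets[[p$scenario %||% "broad"]]
        if (is.null(sc)) stop("unknown scenario preset: ", p$scenario)
        tab <- simulate_population(sc, doses = p$doses %||% c(1, 0.5, 0.1, 0),
                                   horizon = p$horizon %||% 24,
                                   seed = config$seed)
        utils::write.csv(tab, file.path(config$out_dir, "timing.csv"),
                         row.names = FALSE)
        curves <- cumulative_entry_curve(tab, seq(0, p$horizon %||% 24,
                                                  by = 0.25))
        utils::write.csv(curves, file.path(config$out_dir, "curves.csv"),
                         row.names = FALSE)
        tab
      },
      "bifurcation" = {
        pars <- default_params(f_plk1 = p$f_plk1 %||% 1)
        grid <- seq(p$pmin %||% 0.1, p$pmax %||% 8,
                    length.out = p$n_grid %||% 60)
        br <- steady_states(pars, grid)
        utils::write.csv(br, file.path(config$out_dir, "branches.csv"),
                         row.names = FALSE)
        sn <- find_saddle_nodes(pars, bounds = c(p$pmin %||% 0.1,
                                                 p$pmax %||% 8))
        jsonlite::write_json(sn, file.path(config$out_dir,
                                           "saddle_nodes.json"),
                             auto_unbox = TRUE, digits = NA)
        list(branches = br, saddle_nodes = sn)
      },
      "quantify-movie" = {
        cond <- condensation_course(p$movie,
                                    min_area = p$min_area %||% 0,
                                    drop_border = p$drop_border %||% FALSE)
        utils::write.csv(cond, file.path(config$out_dir,
                                         "condensation.csv"),
                         row.names = FALSE)
        cond
      },
      "phospho-run" = {
        args <- p[names(p) %in% c("loc_prob_min", "min_valid_fraction",
                                  "width", "downshift", "align_reference",
                                  "p_cut", "lfc_cut")]
        res <- do.call(phospho_pipeline,
                       c(list(table = p$table, seed = config$seed), args))
        utils::write.csv(res$interaction,
                         file.path(config$out_dir, "interaction.csv"),
                         row.names = FALSE)
        for (nm in names(res$pairwise))
          utils::write.csv(res$pairwise[[nm]],
                           file.path(config$out_dir,
                                     paste0(nm, ".csv")),
                           row.names = FALSE)
        res
      },
      "synth-phospho" = {
        spec <- do.call(phospho_sim_spec, c(p, list(seed = config$seed)))
        g <- generate_phospho(spec)
        utils::write.csv(g$truth, file.path(config$out_dir, "truth.csv"),
                         row.names = FALSE)
        write_phosphosites(g$table, file.path(config$out_dir, "sites.tsv"),
                           file.path(config$out_dir, "design.tsv"))
        g
      },
      "synth-movie" = {
        spec <- do.call(movie_sim_spec, c(p, list(seed = config$seed)))
        g <- generate_movie(spec)
        utils::write.csv(g$truth, file.path(config$out_dir, "truth.csv"),
                         row.names = FALSE)
        g
      })
  }, error = function(e) {
    write_manifest(config, status = paste("error:", conditionMessage(e)))
    stop(e)
  })
  write_manifest(config, status = "ok")
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a phosphosite table as TSV
#'
#' The site-table TSV carries the metadata columns followed by one column
#' per sample; the design TSV carries the sample annotation. Missing
#' intensities are empty fields. MaxQuant-style column names
#' (`Localization prob`, `Potential contaminant`, `Reverse`, `Multiplicity`,
#' `Position`, `Gene names`, `Protein`) are accepted on read.
#'
#' @param table a [phosphosite_table()].
#' @param sites_path,design_path output/input TSV paths.
#' @return `read_phosphosites()`: a [phosphosite_table()].
#' @export
write_phosphosites <- function(table, sites_path, design_path) {
  df <- cbind(table$sites, as.data.frame(table$intensity))
  utils::write.table(df, sites_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$samples, design_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(sites_path)
}

#' @rdname write_phosphosites
#' @param log2 is the intensity data log2-transformed?
#' @export
read_phosphosites <- function(sites_path, design_path, log2 = TRUE) {
  df <- utils::read.delim(sites_path, check.names = FALSE)
  samples <- utils::read.delim(design_path)
  alias <- c("Localization prob" = "loc_prob",
             "Potential contaminant" = "contaminant",
             "Reverse" = "reverse",
             "Multiplicity" = "multiplicity",
             "Position" = "position",
             "Gene names" = "gene",
             "Protein" = "protein",
             "Amino acid" = "residue")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  if (!"id" %in% names(df))
    df$id <- sprintf("site_%05d", seq_len(nrow(df)))
  for (flag in c("contaminant", "reverse")) {
    if (is.character(df[[flag]])) df[[flag]] <- df[[flag]] %in% c("+", "TRUE")
    if (is.null(df[[flag]])) df[[flag]] <- FALSE
  }
  meta_cols <- c("id", "protein", "gene", "residue", "position", "loc_prob",
                 "contaminant", "reverse", "multiplicity")
  intens <- as.matrix(df[, samples$sample, drop = FALSE])
  phosphosite_table(df[, meta_cols], intens, samples, log2 = log2)
}
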