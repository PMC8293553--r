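#' Run a synthetic benchmark end to end
#'
#' For every image of an [experiment_design()], renders the scene, counts
#' tubercles with the supplied pipeline configuration, and matches the
#' detections against the exact ground truth — streaming image by image so
#' full-resolution benchmarks stay within modest memory. The result is the
#' same report [evaluate_experiment()] produces, with the manifest's true
#' counts attached.
#'
#' @param design An [experiment_design()].
#' @param base_params [scene_params()] shared across scenarios.
#' @param config [pipeline_config()] used for counting.
#' @param master_seed Integer master seed (see [generate_experiment()]).
#' @param tolerance_mm Matching tolerance for [match_particles()].
#' @return An `evaluation_report` whose `per_image` table additionally
#'   carries `scenario` and `true_count` columns.
#' @export
run_benchmark <- function(design, base_params = scene_params(),
                          config = pipeline_config(), master_seed = 1L,
                          tolerance_mm = 2) {
  plan <- experiment_plan(design, master_seed)
  rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    p <- scenario_params(base_params, design, plan$scenario[k],
                         plan$true_count[k], plan$seed[k])
    out <- generate_rhizotron_image(p, image_id = plan$image_id[k])
    ps <- count_tubercles(out$image, config, image_id = plan$image_id[k])
    m <- match_particles(ps, out$truth, tolerance_mm = tolerance_mm)
    rows[[k]] <- data.frame(
      image_id = plan$image_id[k], n_truth = nrow(out$truth),
      n_auto = m$tp + m$fp, tp = m$tp, fp = m$fp, fn = m$fn,
      recall = m$recall, precision = m$precision,
      scenario = plan$scenario[k], true_count = plan$true_count[k],
      stringsAsFactors = FALSE)
  }
  assemble_report(do.call(rbind, rows), tolerance_mm)
}
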