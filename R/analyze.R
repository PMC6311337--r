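# Whole-hemipelvis orchestration: plate placement -> tangential screw ->
# cross-sections -> inner/outer searches -> safe region -> pelvimetry.

#' Measure one hemipelvis
#'
#' Runs the full measurement chain on a mesh + landmark pair and returns a
#' `corridor_result`: for the inner screw the maximal anterior/posterior
#' inclination angles (MAIA/MPIA), the screw length L1 at maximal anterior
#' inclination and the medial inclination angle of the insertion plane; for
#' the outer screw MAIA, MPIA and L2; for the obturator-tangential screw its
#' length L0, medial inclination angle (MIA) and anterior/posterior
#' inclination angle (APIA); plus the safe-region pattern and the two
#' auxiliary pelvimetric distances.  Posterior angles are reported negative.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param landmarks a [landmark_set()] on the mesh.
#' @param config a [corridor_config()]; `config$measures` selects the blocks
#'   to run.
#' @return a `corridor_result`.
#' @export
analyze_hemipelvis <- function(mesh, landmarks, config = corridor_config()) {
  require_watertight(mesh, "analyze_hemipelvis")
  mesh <- mesh_with_accel(mesh)
  attr(mesh, "watertight_checked") <- TRUE
  ls <- snap_landmarks(landmarks, mesh)
  O <- ls$symphysis_lowest_O
  brim <- ls$brim
  if (vnorm(brim[1, ] - O) > vnorm(brim[nrow(brim), ] - O)) {
    brim <- brim[rev(seq_len(nrow(brim))), , drop = FALSE]
  }
  mcurve <- ls$tubercle_edge_m
  side_hint <- mcurve[ceiling(nrow(mcurve) / 2), ]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  oc <- stage("plate_placement",
              offset_brim_curve(mesh, brim, config$offset, side_hint))
  ip <- stage("plate_placement",
              locate_insertion_points(mesh, oc, mcurve, config$plate, O))
  hint_M <- -(polyline_nearest(brim, ip$M)$point - ip$M)
  hint_L <- -(polyline_nearest(brim, ip$L)$point - ip$L)
  measures <- config$measures
  res <- list(insertion = ip, landmarks = ls, config = config)

  tng <- NULL
  if (any(c("tangential", "region") %in% measures)) {
    tng <- stage("tangential_screw",
                 tangential_obturator_screw(mesh, ip$L, O, hint_L, config))
  }
  cs <- stage("cross_sections",
              build_cross_sections(mesh, ip$M, ip$L, O, brim,
                                   if (is.null(tng)) NULL else tng$screw$axis))
  res$planes <- cs

  if ("inner" %in% measures) {
    maia <- stage("inner_screw", max_inclination_angle(
      mesh, ip$M, cs$plane3$normal, cs$ref_M_plane3, "anterior", hint_M,
      "max-tangent", config, entry_normal = cs$normal_M))
    mpia <- stage("inner_screw", max_inclination_angle(
      mesh, ip$M, cs$plane3$normal, cs$ref_M_plane3, "posterior", hint_M,
      "fixed-14", config, entry_normal = cs$normal_M))
    pmia <- stage("inner_screw", medial_inclination_angle(
      ip$M, O, cs$ref_M_plane4, cs$plane4$normal))
    res$inner <- list(MAIA = maia$angle_deg, MPIA = mpia$angle_deg,
                      L1 = maia$screw$length, plane_MIA = pmia,
                      screw_anterior = maia$screw, screw_posterior = mpia$screw,
                      brackets = list(MAIA = maia$bracket, MPIA = mpia$bracket))
  }
  if ("outer" %in% measures) {
    maia <- stage("outer_screw", max_inclination_angle(
      mesh, ip$L, cs$plane3$normal, cs$ref_L_plane3par, "anterior", hint_L,
      "max-tangent", config, entry_normal = cs$normal_L))
    mpia <- stage("outer_screw", max_inclination_angle(
      mesh, ip$L, cs$plane3$normal, cs$ref_L_plane3par, "posterior", hint_L,
      "fixed-14", config, entry_normal = cs$normal_L))
    res$outer <- list(MAIA = maia$angle_deg, MPIA = mpia$angle_deg,
                      L2 = maia$screw$length,
                      screw_anterior = maia$screw, screw_posterior = mpia$screw,
                      brackets = list(MAIA = maia$bracket, MPIA = mpia$bracket))
  }
  if (!is.null(tng)) {
    mia <- stage("tangential_screw", measure_angle_in_plane(
      tng$screw$axis, cs$plane2$normal, cs$ref_L_plane2, tng$frame$m))
    apia <- stage("tangential_screw", measure_angle_in_plane(
      tng$screw$axis, cs$plane1$normal, cs$ref_L_plane1, hint_L))
    res$tangential <- list(L0 = tng$L0, MIA = mia, APIA = apia,
                           screw = tng$screw, psi_deg = tng$psi_deg,
                           phi_deg = tng$phi_deg, capped = tng$capped,
                           psi_bracket = tng$psi_bracket)
  }
  if ("region" %in% measures && !is.null(tng)) {
    res$region <- stage("safe_region", safe_region(
      mesh, tng$screw$axis, lateral_hint = -tng$frame$m,
      anterior_hint = hint_L, apex_threshold = config$apex_threshold))
  }
  if ("morphometrics" %in% measures) {
    res$morphometrics <- list(
      symphysis_vertical_distance = symphysis_vertical_distance(ls),
      intertubercular_distance =
        if (!is.null(ls$contralateral_tubercle_apex))
          intertubercular_distance(ls) else NA_real_)
  }
  check_corridor_invariants(res)
  structure(res, class = "corridor_result")
}

check_corridor_invariants <- function(res) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  min_len <- res$config$min_length
  for (nm in c("inner", "outer")) {
    b <- res[[nm]]
    if (is.null(b)) next
    chk(b$MAIA >= 0, sprintf("%s MAIA must be >= 0", nm))
    chk(b$MPIA <= 0, sprintf("%s MPIA must be <= 0", nm))
    chk(b$MAIA > b$MPIA, sprintf("%s MAIA must exceed MPIA", nm))
  }
  if (!is.null(res$inner)) {
    chk(res$inner$L1 >= min_len, "L1 below the minimum screw length")
  }
  if (!is.null(res$outer)) {
    chk(res$outer$L2 >= min_len, "L2 below the minimum screw length")
  }
  if (!is.null(res$tangential)) {
    chk(res$tangential$L0 >= min_len, "L0 below the minimum screw length")
  }
  invisible(TRUE)
}

#' @export
print.corridor_result <- function(x, ...) {
  cat("corridor_result\n")
  if (!is.null(x$inner)) {
    cat(sprintf(
      "  inner screw:      MAIA %6.2f deg  MPIA %7.2f deg  L1 %6.2f mm  plane MIA %5.2f deg\n",
      x$inner$MAIA, x$inner$MPIA, x$inner$L1, x$inner$plane_MIA))
  }
  if (!is.null(x$outer)) {
    cat(sprintf(
      "  outer screw:      MAIA %6.2f deg  MPIA %7.2f deg  L2 %6.2f mm\n",
      x$outer$MAIA, x$outer$MPIA, x$outer$L2))
  }
  if (!is.null(x$tangential)) {
    cat(sprintf(
      "  tangential screw: MIA  %6.2f deg  APIA %7.2f deg  L0 %6.2f mm\n",
      x$tangential$MIA, x$tangential$APIA, x$tangential$L0))
  }
  if (!is.null(x$region)) {
    cat(sprintf("  safe region: %s", x$region$pattern))
    if (!is.na(x$region$apex_angle_deg)) {
      cat(sprintf(" (apex %.1f deg)", x$region$apex_angle_deg))
    }
    cat("\n")
  }
  if (!is.null(x$morphometrics)) {
    cat(sprintf("  symphysis height %.2f mm, intertubercular %.2f mm\n",
                x$morphometrics$symphysis_vertical_distance,
                x$morphometrics$intertubercular_distance))
  }
  invisible(x)
}

#' One-row data frame of a corridor result
#'
#' @param x a `corridor_result`.
#' @param row.names,optional,... passed through for method compatibility.
#' @return a one-row `data.frame` with the measured parameters (angles in
#'   degrees, lengths in mm).
#' @export
as.data.frame.corridor_result <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  g <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  data.frame(
    inner_L1 = g(x$inner$L1), inner_MAIA = g(x$inner$MAIA),
    inner_MPIA = g(x$inner$MPIA), plane_MIA = g(x$inner$plane_MIA),
    outer_L2 = g(x$outer$L2), outer_MAIA = g(x$outer$MAIA),
    outer_MPIA = g(x$outer$MPIA),
    tangential_L0 = g(x$tangential$L0), tangential_MIA = g(x$tangential$MIA),
    tangential_APIA = g(x$tangential$APIA),
    region_pattern = if (is.null(x$region)) NA_character_ else x$region$pattern,
    symphysis_vertical_distance = g(x$morphometrics$symphysis_vertical_distance),
    intertubercular_distance = g(x$morphometrics$intertubercular_distance),
    row.names = row.names, stringsAsFactors = FALSE)
}
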