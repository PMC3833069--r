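# Anthropometry and the reduced planar musculoskeletal model.

#' Subject anthropometry
#'
#' @param subject_id character identifier
#' @param mass body mass (kg), must be positive
#' @param height stature (m), must be positive
#' @param age age (years)
#' @param group `"obese"` or `"normal"`
#' @param walking_speed self-selected walking speed (m/s)
#' @return an object of class `subject_anthropometry`
#' @examples
#' a <- subject_anthropometry("NW01", mass = 43.1, height = 1.506,
#'                            age = 10, group = "normal", walking_speed = 1.22)
#' bmi(a)
#' @export
subject_anthropometry <- function(subject_id, mass, height, age = NA_real_,
                                  group = c("normal", "obese"),
                                  walking_speed = NA_real_) {
  group <- match.arg(group)
  if (!is.finite(mass) || mass <= 0) stop("mass must be positive (kg)")
  if (!is.finite(height) || height <= 0) stop("height must be positive (m)")
  structure(list(subject_id = as.character(subject_id), mass = mass,
                 height = height, age = age, group = group,
                 walking_speed = walking_speed),
            class = "subject_anthropometry")
}

#' Body mass index
#'
#' @param anthro a `subject_anthropometry`
#' @return BMI in kg/m^2
#' @export
bmi <- function(anthro) anthro$mass / anthro$height^2

#' @export
print.subject_anthropometry <- function(x, ...) {
  cat(sprintf("<subject %s> %s, %.1f kg, %.3f m (BMI %.1f), speed %.2f m/s\n",
              x$subject_id, x$group, x$mass, x$height, bmi(x),
              x$walking_speed))
  invisible(x)
}

# Segment mass fractions (Winter), radius-of-gyration fractions (de Leva
# style, about COM) and length fractions of stature for the planar chain.
SEG_TABLE <- data.frame(
  base = c("hat", "thigh", "shank", "foot"),
  mass_frac = c(0.678, 0.100, 0.0465, 0.0145),  # per side for the leg rows
  len_frac = c(0.400, 0.245, 0.246, 0.152),
  com_offset = c(0.550, 0.433, 0.433, 0.500),   # fraction from proximal end
  k_frac = c(0.496, 0.323, 0.302, 0.475),       # rog / segment length
  stringsAsFactors = FALSE
)

# Muscle-group table for the generic model.  Moment arms (m, at the generic
# 1.50 m stature) are signed in the coordinate conventions: hip/knee flexion
# positive, ankle dorsiflexion positive.  f_max scales with body mass.
MUSCLE_TABLE <- data.frame(
  name = c("glut_max", "iliopsoas", "hamstrings", "rect_fem",
           "vasti", "gastroc", "soleus", "dorsiflex"),
  group = c("gluteus_maximus", "iliopsoas", "hamstrings", "quadriceps",
            "quadriceps", "gastrocnemius", "soleus", "dorsiflexors"),
  fmax_per_kg = c(36, 29, 34, 16, 60, 30, 47, 22),  # N per kg body mass
  # glut_max folds in the posterior gluteus medius sagittal capacity
  # (no frontal-plane actuator in a planar model); hamstrings counts the
  # hip-extending heads only
  arm_hip = c(-0.060, 0.045, -0.055, 0.040, 0, 0, 0, 0),
  arm_knee = c(0, 0, 0.030, -0.042, -0.042, 0.020, 0, 0),
  arm_ankle = c(0, 0, 0, 0, 0, -0.048, -0.048, 0.037),
  biarticular = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

GENERIC_HEIGHT <- 1.50  # m, reference stature for moment arms / geometry

#' Generic (unscaled) planar gait model
#'
#' A 9-DOF sagittal-plane model: head-arms-trunk (HAT, pelvis included),
#' thigh, shank and foot per side; revolute hip, knee (flexion/extension
#' only) and ankle; eight lumped Hill-type muscle groups per leg with
#' rigid-tendon, activation-scaled force (F = a * f_max) and constant signed
#' moment arms.  Segment masses, lengths and inertias are standard
#' anthropometric fractions of body mass and stature.
#'
#' @return an unscaled `gait_model` template (use [scale_model()] before any
#'   mechanics)
#' @seealso [scale_model()]
#' @export
generic_model <- function() {
  structure(list(
    subject = NULL,
    seg_table = SEG_TABLE,
    muscle_table = MUSCLE_TABLE,
    generic_height = GENERIC_HEIGHT,
    gravity = c(0, -9.81)
  ), class = "gait_model_generic")
}

#' Scale the generic model to a subject
#'
#' Segment lengths scale with stature, segment masses with body mass (fixed
#' fractions: HAT 0.678, thigh 0.100/side, shank 0.0465/side, foot
#' 0.0145/side), inertias with mass x length^2, maximal isometric forces
#' with body mass, moment arms and attachment geometry with stature.
#'
#' @param anthro a [subject_anthropometry()]
#' @param generic output of [generic_model()] (default)
#' @return a scaled `gait_model` ready for the mechanics pipeline
#' @examples
#' m <- scale_model(subject_anthropometry("NW", 43.1, 1.506))
#' sum(sapply(m$segments, `[[`, "mass"))  # == 43.1
#' @export
scale_model <- function(anthro, generic = generic_model()) {
  if (!inherits(anthro, "subject_anthropometry"))
    stop("anthro must be a subject_anthropometry")
  st <- generic$seg_table
  H <- anthro$height; W <- anthro$mass
  hs <- H / generic$generic_height  # geometry scale factor

  seg_one <- function(base) {
    row <- st[st$base == base, ]
    L <- row$len_frac * H
    m <- row$mass_frac * W
    list(mass = m, length = L, com_offset = row$com_offset,
         inertia = m * (row$k_frac * L)^2)
  }
  segments <- list(hat = seg_one("hat"))
  for (base in c("thigh", "shank", "foot"))
    for (side in c("r", "l"))
      segments[[paste0(base, "_", side)]] <- seg_one(base)

  Lf <- segments$foot_r$length
  geometry <- list(
    ankle_height = 0.039 * H,
    ankle_from_heel = 0.25,            # fraction of foot length
    hat_length = segments$hat$length,
    height_scale = hs,
    # muscle attachment points, local frames (see point_spec), at stature H
    attach = list(
      patella_thigh = c(0.043 * hs, -(st$len_frac[st$base == "thigh"] * H - 0.02 * hs)),
      tib_tuberosity_shank = c(0.035 * hs, -0.08 * hs),
      ham_insert_shank = c(-0.025 * hs, -0.055 * hs),
      ham_origin_hat = c(-0.07 * hs, -0.02 * hs),
      gastroc_origin_thigh = c(-0.025 * hs,
                               -(st$len_frac[st$base == "thigh"] * H - 0.035 * hs)),
      calcaneus_foot = c(-0.24 * Lf, -0.3 * 0.039 * H),
      soleus_origin_shank = c(-0.02 * hs, -0.25 * st$len_frac[st$base == "shank"] * H),
      dorsi_origin_shank = c(0.025 * hs, -0.35 * st$len_frac[st$base == "shank"] * H),
      dorsi_insert_foot = c(0.25 * Lf, -0.5 * 0.039 * H),
      glut_origin_hat = c(-0.08 * hs, 0.05 * hs),
      glut_insert_thigh = c(-0.015 * hs, -0.25 * st$len_frac[st$base == "thigh"] * H),
      psoas_origin_hat = c(0.05 * hs, 0.05 * hs),
      psoas_insert_thigh = c(0.015 * hs, -0.12 * st$len_frac[st$base == "thigh"] * H),
      rf_origin_hat = c(0.06 * hs, 0.02 * hs),
      vasti_origin_thigh = c(0.02 * hs, -0.30 * st$len_frac[st$base == "thigh"] * H)
    )
  )

  mt <- generic$muscle_table
  muscles <- list()
  for (side in c("r", "l")) {
    for (i in seq_len(nrow(mt))) {
      arms <- c(mt$arm_hip[i], mt$arm_knee[i], mt$arm_ankle[i]) * hs
      names(arms) <- paste0(c("hip_", "knee_", "ankle_"), side)
      att <- muscle_attachments(mt$name[i], side, geometry)
      muscles[[paste0(mt$name[i], "_", side)]] <- list(
        name = paste0(mt$name[i], "_", side), base = mt$name[i],
        group = mt$group[i], side = side,
        f_max = mt$fmax_per_kg[i] * W,
        arms = arms[arms != 0],
        biarticular = mt$biarticular[i],
        origin = att$origin, insertion = att$insertion, via = att$via)
    }
  }

  model <- structure(list(
    subject = anthro, segments = segments, geometry = geometry,
    muscles = muscles, coords = GAIT_COORDS, gravity = generic$gravity
  ), class = "gait_model")
  validate_model(model)
  model
}

# Attachment geometry (origin / insertion / optional via target) per muscle.
muscle_attachments <- function(base, side, geom) {
  a <- geom$attach
  seg <- function(b) if (b == "hat") "hat" else paste0(b, "_", side)
  switch(base,
    glut_max = list(origin = list(segment = "hat", local = a$glut_origin_hat),
                    insertion = list(segment = seg("thigh"),
                                     local = a$glut_insert_thigh), via = NULL),
    iliopsoas = list(origin = list(segment = "hat", local = a$psoas_origin_hat),
                     insertion = list(segment = seg("thigh"),
                                      local = a$psoas_insert_thigh), via = NULL),
    hamstrings = list(origin = list(segment = "hat", local = a$ham_origin_hat),
                      insertion = list(segment = seg("shank"),
                                       local = a$ham_insert_shank), via = NULL),
    rect_fem = list(origin = list(segment = "hat", local = a$rf_origin_hat),
                    insertion = list(segment = seg("shank"),
                                     local = a$tib_tuberosity_shank),
                    via = list(segment = seg("thigh"), local = a$patella_thigh)),
    vasti = list(origin = list(segment = seg("thigh"), local = a$vasti_origin_thigh),
                 insertion = list(segment = seg("shank"),
                                  local = a$tib_tuberosity_shank),
                 via = list(segment = seg("thigh"), local = a$patella_thigh)),
    gastroc = list(origin = list(segment = seg("thigh"),
                                 local = a$gastroc_origin_thigh),
                   insertion = list(segment = seg("foot"),
                                    local = a$calcaneus_foot), via = NULL),
    soleus = list(origin = list(segment = seg("shank"),
                                local = a$soleus_origin_shank),
                  insertion = list(segment = seg("foot"),
                                   local = a$calcaneus_foot), via = NULL),
    dorsiflex = list(origin = list(segment = seg("shank"),
                                   local = a$dorsi_origin_shank),
                     insertion = list(segment = seg("foot"),
                                      local = a$dorsi_insert_foot), via = NULL),
    stop("unknown muscle base: ", base))
}

validate_model <- function(model) {
  stopifnot(length(model$coords) == 9L)
  msum <- total_mass(model)
  if (abs(msum - model$subject$mass) > 1e-9 * model$subject$mass)
    stop("segment masses do not sum to subject mass")
  for (m in model$muscles) {
    if (m$f_max <= 0) stop("non-positive f_max for ", m$name)
    if (any(abs(m$arms) > 0.12))
      stop("moment arm out of physiological bound for ", m$name)
    bad <- setdiff(names(m$arms), model$coords)
    if (length(bad)) stop("muscle ", m$name, " spans unknown coordinate ", bad)
    if (m$biarticular && length(m$arms) < 2L)
      stop("biarticular muscle ", m$name, " must span >= 2 joints")
  }
  invisible(TRUE)
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf(
    "<gait_model> planar 9-DOF, %d segments, %d muscle-tendon units\n",
    length(x$segments), length(x$muscles)))
  if (!is.null(x$subject))
    cat(sprintf("  scaled to %s: %.1f kg, %.3f m\n",
                x$subject$subject_id, x$subject$mass, x$subject$height))
  invisible(x)
}

#' Moment arm of a muscle about a coordinate
#'
#' Constant by default; a muscle definition may carry an `arm_poly` list
#' (named by coordinate) of polynomial coefficients in the joint angle
#' (rad), added to the constant term, for angle-dependent arms.
#'
#' @param muscle a muscle definition from a `gait_model`
#' @param coord coordinate name, e.g. `"knee_r"`
#' @param angle joint angle (rad)
#' @return signed moment arm (m); 0 if the muscle does not span the joint
#' @export
moment_arm <- function(muscle, coord, angle = 0) {
  a0 <- muscle$arms[coord]
  if (is.na(a0)) return(rep(0, length(angle)))
  out <- rep(unname(a0), length(angle))
  pc <- muscle$arm_poly[[coord]]
  if (!is.null(pc))
    for (k in seq_along(pc)) out <- out + pc[k] * angle^k
  out
}

#' Classify a subject's BMI against an age/sex cut-off table
#'
#' Pediatric obesity is classified with age- and sex-specific BMI
#' cut-offs; the cut-off values themselves must be supplied (they are not
#' part of this package's defaults).  A *synthetic example* table ships at
#' `system.file("extdata", "bmi_cutoffs_synthetic.csv", package = "gaitsim")`.
#'
#' @param anthro a [subject_anthropometry()]
#' @param cutoff_table data.frame with columns `age`, `sex`, `overweight`,
#'   `obese` (BMI thresholds, kg/m^2); ages are matched on `floor(age)`
#' @param sex subject sex used for the lookup (default `"male"`)
#' @return `"obese"`, `"other"` (overweight) or `"normal"`
#' @export
classify_bmi <- function(anthro, cutoff_table, sex = "male") {
  if (!is.data.frame(cutoff_table) || nrow(cutoff_table) == 0L)
    stop("cutoff_table must be a non-empty data.frame")
  need <- c("age", "sex", "overweight", "obese")
  miss <- setdiff(need, names(cutoff_table))
  if (length(miss)) stop("cutoff_table lacks columns: ",
                         paste(miss, collapse = ", "))
  row <- cutoff_table[cutoff_table$age == floor(anthro$age) &
                        cutoff_table$sex == sex, , drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("no cut-off row for age %d, sex %s",
                 as.integer(floor(anthro$age)), sex))
  b <- bmi(anthro)
  if (b >= row$obese[1L]) "obese"
  else if (b >= row$overweight[1L]) "other"
  else "normal"
}
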