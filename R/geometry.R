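#' Geometry of a two-lead epidural electrode arrangement
#'
#' Describes two 8-contact cylindrical leads placed along the rostro-caudal
#' axis of the spinal cord, plus a remote reference electrode sitting in
#' non-neural tissue (e.g. the paravertebral muscles). Contacts are numbered
#' 1--16; within each lead a higher contact number is more caudal. Contacts on
#' the first (stimulation) lead are 1--8, on the second (recording) lead 9--16,
#' so contact 9 is the most rostral contact of the arrangement and contact 16
#' the most caudal contact of the recording lead.
#'
#' The rostro-caudal coordinate increases rostrally, with the most caudal
#' contact (contact 8) at 0 mm. The stimulating pair defaults to contacts 7
#' and 8, so the stimulation site (their midpoint) sits at `pitch / 2` mm.
#'
#' @param n_leads Number of leads; only the two-lead arrangement is supported.
#' @param contacts_per_lead Contacts on each lead (default 8).
#' @param contact_length_mm Contact length in mm (default 3).
#' @param contact_spacing_mm Gap between contacts in mm (default 4); the
#'   center-to-center pitch is `contact_length_mm + contact_spacing_mm`.
#' @param inter_lead_gap_mm Center-to-center distance (mm) between the most
#'   rostral contact of the stimulation lead (contact 1) and the most caudal
#'   contact of the recording lead (contact 16). The default 7 continues the
#'   within-lead pitch, i.e. the leads lie in series.
#' @param stim_anode,stim_cathode Stimulating contact indices; must be
#'   adjacent contacts on the same lead (defaults 7 and 8).
#' @param lateral_offset_mm Length-2 numeric: medio-lateral offset of each
#'   lead from the cord midline, mm (default both 0).
#' @param recording_offset_mm Optional override: axial distance (mm) from the
#'   stimulation site to the most caudal recording-lead contact (contact 16).
#'   When supplied it replaces the placement implied by `inter_lead_gap_mm`,
#'   e.g. to park the recording contacts closer to the stimulation site than
#'   an in-series arrangement allows.
#'
#' @return An object of class `esr_geometry`: a list with the scalar fields
#'   above plus `pitch_mm`, `stim_center_mm` and `contacts`, a tibble with one
#'   row per contact (`contact`, `lead`, `pos_mm`, `lateral_mm`, `is_stim`,
#'   `distance_mm` = axial distance to the stimulation site).
#' @examples
#' geo <- lead_geometry()
#' geo$contacts
#' @export
lead_geometry <- function(n_leads = 2,
                          contacts_per_lead = 8,
                          contact_length_mm = 3,
                          contact_spacing_mm = 4,
                          inter_lead_gap_mm = 7,
                          stim_anode = 7,
                          stim_cathode = 8,
                          lateral_offset_mm = c(0, 0),
                          recording_offset_mm = NULL) {
  if (n_leads != 2) {
    rlang::abort("only the two-lead arrangement is supported", class = "esrkit_error_geometry")
  }
  pitch <- contact_length_mm + contact_spacing_mm
  n <- contacts_per_lead
  if (length(lateral_offset_mm) == 1) lateral_offset_mm <- rep(lateral_offset_mm, 2)

  # lead 1: contact n (most caudal) at 0; higher index = more caudal
  pos1 <- (n - seq_len(n)) * pitch
  if (abs(stim_anode - stim_cathode) != 1 || any(!c(stim_anode, stim_cathode) %in% seq_len(n))) {
    rlang::abort("stimulating contacts must be adjacent contacts on the first lead",
      class = "esrkit_error_geometry"
    )
  }
  stim_center <- mean(pos1[c(stim_anode, stim_cathode)])

  if (is.null(recording_offset_mm)) {
    pos16 <- pos1[1] + inter_lead_gap_mm
  } else {
    if (recording_offset_mm <= 0) {
      rlang::abort("recording_offset_mm must be positive", class = "esrkit_error_geometry")
    }
    pos16 <- stim_center + recording_offset_mm
  }
  # lead 2: contact 2n most caudal, contact n+1 most rostral
  pos2 <- pos16 + (rev(seq_len(n)) - 1) * pitch

  contacts <- tibble::tibble(
    contact = seq_len(2 * n),
    lead = rep(1:2, each = n),
    pos_mm = c(pos1, pos2),
    lateral_mm = rep(lateral_offset_mm, each = n),
    is_stim = seq_len(2 * n) %in% c(stim_anode, stim_cathode)
  )
  contacts$distance_mm <- abs(contacts$pos_mm - stim_center)

  geo <- structure(
    list(
      n_leads = 2L,
      contacts_per_lead = as.integer(n),
      contact_length_mm = contact_length_mm,
      contact_spacing_mm = contact_spacing_mm,
      pitch_mm = pitch,
      inter_lead_gap_mm = inter_lead_gap_mm,
      stim_anode = as.integer(stim_anode),
      stim_cathode = as.integer(stim_cathode),
      stim_center_mm = stim_center,
      contacts = contacts
    ),
    class = "esr_geometry"
  )
  validate_geometry(geo)
  geo
}

validate_geometry <- function(geo) {
  stopifnot(inherits(geo, "esr_geometry"))
  if (!isTRUE(all.equal(geo$pitch_mm, geo$contact_length_mm + geo$contact_spacing_mm))) {
    rlang::abort("pitch must equal contact length + spacing", class = "esrkit_error_geometry")
  }
  by_lead <- split(geo$contacts$pos_mm, geo$contacts$lead)
  ok <- vapply(by_lead, function(p) all(diff(p) < 0) || all(diff(p) > 0), logical(1))
  if (!all(ok)) {
    rlang::abort("contact positions must be strictly monotone along each lead",
      class = "esrkit_error_geometry"
    )
  }
  invisible(geo)
}

#' Displace one lead of a geometry
#'
#' Returns a new geometry with one lead translated along the rostro-caudal
#' and/or medio-lateral axis; the input is not modified. Used to model lead
#' migration between recording sessions (e.g. rostral shifts of 3.5, 28 or
#' 52.5 mm, or a lateral shift of 3.5 mm).
#'
#' @param geometry An [lead_geometry()] object.
#' @param which_lead 1 or 2.
#' @param delta_rostral_mm Rostral (+) / caudal (-) displacement, mm.
#' @param delta_lateral_mm Medio-lateral displacement, mm.
#' @return A new `esr_geometry`. Errors if the displaced lead would overlap
#'   the other lead (same lateral track and intersecting axial extents).
#' @examples
#' shifted <- shift_lead(lead_geometry(), 2, delta_rostral_mm = 3.5)
#' @export
shift_lead <- function(geometry, which_lead, delta_rostral_mm, delta_lateral_mm = 0) {
  stopifnot(inherits(geometry, "esr_geometry"), which_lead %in% 1:2)
  geo <- geometry
  sel <- geo$contacts$lead == which_lead
  geo$contacts$pos_mm[sel] <- geo$contacts$pos_mm[sel] + delta_rostral_mm
  geo$contacts$lateral_mm[sel] <- geo$contacts$lateral_mm[sel] + delta_lateral_mm

  half <- geo$contact_length_mm / 2
  span <- function(l) range(geo$contacts$pos_mm[geo$contacts$lead == l]) + c(-half, half)
  lat <- function(l) geo$contacts$lateral_mm[geo$contacts$lead == l][1]
  s1 <- span(1); s2 <- span(2)
  overlap <- s1[1] <= s2[2] && s2[1] <= s1[2] && isTRUE(all.equal(lat(1), lat(2)))
  if (overlap) {
    rlang::abort("shifted lead would overlap the other lead", class = "esrkit_error_geometry")
  }

  if (which_lead == 1) {
    geo$stim_center_mm <- mean(geo$contacts$pos_mm[geo$contacts$is_stim])
  }
  geo$contacts$distance_mm <- abs(geo$contacts$pos_mm - geo$stim_center_mm)
  validate_geometry(geo)
  geo
}

#' @export
print.esr_geometry <- function(x, ...) {
  cat(sprintf(
    "<esr_geometry> 2 leads x %d contacts, pitch %.1f mm, stim contacts %d/%d at %.1f mm\n",
    x$contacts_per_lead, x$pitch_mm, x$stim_anode, x$stim_cathode, x$stim_center_mm
  ))
  print(x$contacts, n = 4)
  invisible(x)
}

#' Expected ECAP delay between adjacent contacts
#'
#' The propagation delay of an evoked compound action potential between two
#' neighbouring contacts is simply pitch / velocity; at the standard 7 mm
#' pitch and an A-beta-range velocity of 70 m/s this is 0.1 ms.
#'
#' @param pitch_mm Contact center-to-center pitch, mm.
#' @param velocity_m_per_s Conduction velocity, m/s.
#' @return Delay in ms.
#' @examples
#' adjacent_contact_delay(7, 70) # 0.1 ms
#' @export
adjacent_contact_delay <- function(pitch_mm, velocity_m_per_s) {
  stopifnot(velocity_m_per_s > 0)
  pitch_mm / velocity_m_per_s
}
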