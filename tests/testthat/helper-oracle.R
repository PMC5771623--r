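# Independent straight-line evaluation of every index formula, written
# directly from the printed equations and kept deliberately separate from
# the registry's expression functions. Band resolution is shared plumbing
# (nearest-channel lookup); the arithmetic is re-coded here.

oracle_indices <- function(s) {
  R <- function(nm) band_value(s, nm)
  D <- function(nm) derivative_value(s, nm)
  nd <- function(a, b) (R(a) - R(b)) / (R(a) + R(b))
  out <- c(
    NDVI1 = nd(800, 670), NDVI2 = nd(780, 670), NDVI3 = nd(573, 440),
    NDVI4 = nd(410, 365), NDVI5 = nd(503, 483), NDVI6 = nd(800, 680),
    NDVI7 = nd(1220, 710), NDVI8 = nd(801, 550),
    NDI1 = nd(790, 720), NDI2 = nd(860, 720), NDI3 = nd(750, 705),
    NDI4 = nd(570, 531),
    NDI5 = (R(780) - R(710)) / (R(780) - R(680)),
    NDI6 = (R(850) - R(710)) / (R(850) - R(680)),
    NDI7 = (R(734) - R(747)) / (R(715) + R(726)),
    mNDI = (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445)),
    SR1 = R(700) / R(670), SR2 = R(750) / R(550), SR3 = R(750) / R(700),
    SR4 = R(780) / R(670), SR5 = R(787) / R(765), SR6 = R(553) / R(537),
    SR7 = R(545) / R(538), SR8 = R(554) / R(677), SR9 = R(801) / R(670),
    SR10 = R(800) / R(550), SR11 = R(740) / R(720),
    SR12 = R(670) / (R(700) * R(650)),
    SR13 = R(672) / (R(708) * R(550)),
    SR14 = R(860) / (R(708) * R(550)),
    PSSRa = R(800) / R(680), PSSRb = R(800) / R(635),
    SR15 = R(750) / R(705), SR16 = R(950) / R(660),
    SR17 = R(990) / R(720), SR18 = R(780) / R(740),
    SR19 = D(743) / D(1316), SR20 = D(730) / D(705),
    ZTM = R(760) / R(710), VIopt2 = R(760) / R(730),
    MSR1 = (R(800) / R(670) - 1) / sqrt(R(800) / R(670) + 1),
    MSR2 = (R(750) / R(705) - 1) / sqrt(R(750) / R(705) + 1),
    CARI = (R(700) - R(670)) - 0.2 * (R(700) + R(550)),
    MCARI1 = ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) * (R(700) / R(670)),
    MCARI2 = ((R(750) - R(705)) - 0.2 * (R(750) - R(550))) * (R(750) / R(705)),
    TCARI = 3 * ((R(700) - R(670)) - 0.2 * (R(700) - R(550)) * (R(700) / R(670))),
    TVI = 0.5 * (120 * (R(750) - R(550)) - 200 * (R(670) - R(550))),
    MTVI1 = 1.2 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))),
    MTVI2 = 1.5 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))) /
      sqrt((2 * R(800) + 1)^2 - (6 * R(800) - 5 * sqrt(R(670))) - 0.5),
    REP = 710 + 50 * (0.5 * (R(810) + R(660)) - R(710)) / (R(760) - R(710)),
    OSAVI1 = (1 + 0.16) * (R(800) - R(670)) / (R(800) + R(670) + 0.16),
    OSAVI2 = (1 + 0.16) * (R(750) - R(705)) / (R(750) + R(705) + 0.16),
    MSAVI = 0.5 * (2 * R(800) + 1 -
                     sqrt((2 * R(800) + 1)^2 - 8 * (R(800) - R(670)))),
    TBI1 = R(705) / (R(717) + R(491)),
    TBI2 = R(1310) / (R(1720) + R(730)),
    TBI3 = (R(924) - R(703) + 2 * R(423)) / (R(924) + R(703) - 2 * R(423)),
    R_M = R(750) / R(720) - 1,
    G_M = R(750) / R(550) - 1,
    PNC = exp(2.5 - 23.5 * (R(503) - R(483)) / (R(503) + R(483)))
  )
  ratios <- c(
    TCARI_OSAVI1 = out[["TCARI"]] / out[["OSAVI1"]],
    TCARI_OSAVI2 = out[["TCARI"]] / out[["OSAVI2"]],
    CARI_OSAVI1 = out[["CARI"]] / out[["OSAVI1"]],
    CARI_OSAVI2 = out[["CARI"]] / out[["OSAVI2"]],
    MCARI1_OSAVI1 = out[["MCARI1"]] / out[["OSAVI1"]],
    MCARI1_OSAVI2 = out[["MCARI1"]] / out[["OSAVI2"]],
    MCARI2_OSAVI1 = out[["MCARI2"]] / out[["OSAVI1"]],
    MCARI2_OSAVI2 = out[["MCARI2"]] / out[["OSAVI2"]]
  )
  c(out, ratios)
}

# Max relative deviation between registry and oracle on one spectrum.
oracle_max_rel_dev <- function(s, catalog = builtin_index_catalog()) {
  expected <- oracle_indices(s)
  got <- vapply(catalog, function(d) compute_index(s, d), numeric(1))
  stopifnot(setequal(names(expected), names(got)))
  expected <- expected[names(got)]
  max(abs(got - expected) / pmax(abs(expected), 1e-12))
}
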