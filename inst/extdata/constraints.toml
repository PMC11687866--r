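# Blood-tissue exchange constraint configuration.
# Fluxes in pmol/s/mm2 of retinal surface.

[oxygen]
# macaque outer-retina oxygen uptake from oxygen-profile measurements
macaque.perifovea.light = 2.46
macaque.perifovea.dark = 3.74
macaque.fovea.light = 2.34
macaque.fovea.dark = 2.72
# share of perifoveal PR oxygen supplied by the retinal circulation
inner_retina_fraction.light = 0.11
inner_retina_fraction.dark = 0.15
# RPE oxygen consumption add-on (plate respirometry, ~200 pmol/min over
# an 11 mm2 well)
rpe_addon = 0.30
# fixed interface oxygen transfer (supplementary-table constant);
# NA leaves the transfer unconstrained
interface_transfer = NA

[glucose_lactate]
# SYNTHETIC stand-ins for the arteriovenous-derived per-area fluxes
# (the source tables are not reproduced here); override with measured
# values where available
glucose_uptake.perifovea.light = 2.0
glucose_uptake.perifovea.dark = 4.6
glucose_uptake.fovea.light = 1.7
glucose_uptake.fovea.dark = 3.3
lactate_export.perifovea.light = 4.75
lactate_export.perifovea.dark = 8.2
lactate_export.fovea.light = 3.8
lactate_export.fovea.dark = 5.8

[fick]
# oxygen diffusion constants for the theoretical maximum flux
D = 1.97e-5
alpha = 1.38
delta_P = 100
f = 0.7
L.perifovea = 58
L.fovea = 77

[cat_geometry]
radius = 11
retina_fraction = 0.65
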