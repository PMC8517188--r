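# Example machine configuration consumed by readMachineConfig().
# Boundaries are leaf-pair edges at the isocenter plane (mm).
TrueBeam:
  leaf_boundaries: [-200, -190, -180, -170, -160, -150, -140, -130, -120,
                    -110, -100, -95, -90, -85, -80, -75, -70, -65, -60, -55,
                    -50, -45, -40, -35, -30, -25, -20, -15, -10, -5, 0, 5,
                    10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75,
                    80, 85, 90, 95, 100, 110, 120, 130, 140, 150, 160, 170,
                    180, 190, 200]
  max_dose_rate: 600
  max_gantry_speed: 6.0
  max_leaf_speed: 2.5
  min_leaf_gap: 2.0
Halcyon:
  leaf_boundaries: [-142.5, -137.5, -132.5, -127.5, -122.5, -117.5, -112.5,
                    -107.5, -102.5, -97.5, -92.5, -87.5, -82.5, -77.5,
                    -72.5, -67.5, -62.5, -57.5, -52.5, -47.5, -42.5, -37.5,
                    -32.5, -27.5, -22.5, -17.5, -12.5, -7.5, -2.5, 2.5, 7.5,
                    12.5, 17.5, 22.5, 27.5, 32.5, 37.5, 42.5, 47.5, 52.5,
                    57.5, 62.5, 67.5, 72.5, 77.5, 82.5, 87.5, 92.5, 97.5,
                    102.5, 107.5, 112.5, 117.5, 122.5, 127.5, 132.5, 137.5,
                    142.5]
  max_dose_rate: 800
  max_gantry_speed: 6.0
  max_leaf_speed: 2.5
  min_leaf_gap: 2.0
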