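# Canonical PBAE descriptor schema: name -> source tag + unit.
# Sources: amine / acrylate = computed per-monomer database descriptors;
# repeat_unit = properties of the amine+acrylate repeat unit;
# experimental = measured on the synthesized polymer.
amine_logP:            {source: amine, unit: unitless}
amine_TPSA:            {source: amine, unit: A^2}
amine_complexity:      {source: amine, unit: unitless}
amine_heavy_atoms:     {source: amine, unit: count}
amine_volume_3d:       {source: amine, unit: A^3}
amine_x_quadrupole:    {source: amine, unit: unitless}
amine_y_quadrupole:    {source: amine, unit: unitless}
amine_z_quadrupole:    {source: amine, unit: unitless}
acrylate_logP:         {source: acrylate, unit: unitless}
acrylate_TPSA:         {source: acrylate, unit: A^2}
acrylate_complexity:   {source: acrylate, unit: unitless}
acrylate_heavy_atoms:  {source: acrylate, unit: count}
acrylate_volume_3d:    {source: acrylate, unit: A^3}
acrylate_x_quadrupole: {source: acrylate, unit: unitless}
acrylate_y_quadrupole: {source: acrylate, unit: unitless}
acrylate_z_quadrupole: {source: acrylate, unit: unitless}
repeat_MW:             {source: repeat_unit, unit: Da}
repeat_BP:             {source: repeat_unit, unit: degC}
repeat_MP:             {source: repeat_unit, unit: degC}
repeat_critical_volume: {source: repeat_unit, unit: cm^3/mol}
repeat_gibbs_energy:   {source: repeat_unit, unit: kJ/mol}
repeat_logP:           {source: repeat_unit, unit: unitless}
repeat_logS:           {source: repeat_unit, unit: unitless}
repeat_pKa:            {source: repeat_unit, unit: unitless}
repeat_molar_refractivity: {source: repeat_unit, unit: cm^3/mol}
repeat_heat_formation: {source: repeat_unit, unit: kJ/mol}
repeat_TPSA:           {source: repeat_unit, unit: A^2}
poly_Mw:               {source: experimental, unit: Da}
poly_Mn:               {source: experimental, unit: Da}
poly_zeta_potential:   {source: experimental, unit: mV}
poly_size:             {source: experimental, unit: nm}
poly_drug_loading:     {source: experimental, unit: w/w}
poly_diffusion_coefficient: {source: experimental, unit: mm^2/min}
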