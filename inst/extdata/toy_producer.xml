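<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="A" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="gA_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="c_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="byp_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="byp_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="EX_gA_e_lb" value="             -1000" constant="true"/>
      <parameter id="EX_gA_e_ub" value="              1000" constant="true"/>
      <parameter id="T_gA_lb" value="                 0" constant="true"/>
      <parameter id="T_gA_ub" value="              1000" constant="true"/>
      <parameter id="BIOMASS_lb" value="                 0" constant="true"/>
      <parameter id="BIOMASS_ub" value="              1000" constant="true"/>
      <parameter id="T_byp_lb" value="                 0" constant="true"/>
      <parameter id="T_byp_ub" value="              1000" constant="true"/>
      <parameter id="EX_byp_e_lb" value="             -1000" constant="true"/>
      <parameter id="EX_byp_e_ub" value="              1000" constant="true"/>
      <parameter id="CONV_lb" value="                 0" constant="true"/>
      <parameter id="CONV_ub" value="              1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_gA_e" reversible="true" fast="false" fbc:lowerFluxBound="EX_gA_e_lb" fbc:upperFluxBound="EX_gA_e_ub">
        <listOfReactants>
          <speciesReference species="gA_e" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="T_gA" reversible="false" fast="false" fbc:lowerFluxBound="T_gA_lb" fbc:upperFluxBound="T_gA_ub">
        <listOfReactants>
          <speciesReference species="gA_e" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="c_c" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false" fbc:lowerFluxBound="BIOMASS_lb" fbc:upperFluxBound="BIOMASS_ub">
        <listOfReactants>
          <speciesReference species="c_c" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="byp_c" stoichiometry="0.10000000000000001" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="T_byp" reversible="false" fast="false" fbc:lowerFluxBound="T_byp_lb" fbc:upperFluxBound="T_byp_ub">
        <listOfReactants>
          <speciesReference species="byp_c" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="byp_e" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_byp_e" reversible="true" fast="false" fbc:lowerFluxBound="EX_byp_e_lb" fbc:upperFluxBound="EX_byp_e_ub">
        <listOfReactants>
          <speciesReference species="byp_e" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="CONV" reversible="false" fast="false" fbc:lowerFluxBound="CONV_lb" fbc:upperFluxBound="CONV_ub">
        <listOfReactants>
          <speciesReference species="c_c" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="byp_c" stoichiometry="               0.5" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="                 1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
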