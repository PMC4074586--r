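<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic three-reaction chain model (uptake -> conversion -> biomass)
     in SBML Level 3 + FBC v2, with an explicit boundary species on the
     exchange. Hand-written test fixture, not derived from any published
     reconstruction. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_chain_synthetic" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" compartment="e" boundaryCondition="true"
               hasOnlySubstanceUnits="false" constant="false"/>
      <species id="A" compartment="c" boundaryCondition="false"
               hasOnlySubstanceUnits="false" constant="false"/>
      <species id="B" compartment="c" boundaryCondition="false"
               hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="GRO" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GRO" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
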