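# Sensory-motor substage 4: tracking and searching. Extends the tracking
# circuit: when the toy disappears (attention halts at the occluder after a
# diversion), a search thread is driven through a pathway potentiated by an
# LTP whose coincidence trigger is the diversion itself. Run with weak
# plasticity the pathway binds to its first ground instantiation and a
# second hiding reproduces the A-not-B error; with strong plasticity the
# search rebinds and follows the displacement. A signal that the object has
# been uncovered (view after a search) drives the grasping reflex through a
# short-term potentiation from the search thread.
circuit searching
stream main
node sensor main s_move move(obj(P,X))
node internal main expect expect(obj(P,X+1)) ttl=2
node sensor main s_see see(obj(Q,X+1))
node internal main cont cont(obj(P,X+1)) ttl=2
node internal main divert divert(obj(Q,X+1))
node sensor main s_halt halt(T)
node effector main grasp grasp(obj(P,X+1))
node effector main look look(obj(Q,X+1))
node effector main search search(T)
node sensor main s_view view(obj(P,X))
edge synapse s_move expect
edge conj expect cont w=0 plasticity=stp:expect:2 choice=attend
edge conj s_see cont as=see(obj(P,X+1))
edge conj expect divert w=0 plasticity=stp:expect:2 as=expect(obj(P0,X+1)) choice=attend
edge conj s_see divert
edge synapse divert look
edge conj cont grasp
edge conj s_halt grasp as=halt(obj(P,X+1))
edge synapse s_halt search w=0 plasticity=ltp:divert
edge synapse s_view grasp w=0 payload=grasp(obj(P,X)) plasticity=stp:search:2
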